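#' Save and load fitted ELM models as JSON
#'
#' Writes every component needed to reproduce decision scores exactly:
#' the kernel specification, reference points (or random-feature
#' weights), output weights, regulation coefficient, standardiser and
#' label map, plus a format version.  `wkelm_load()` of a saved model
#' yields identical scores on any input.
#'
#' @param model A fitted [wkelm()] model.
#' @param path Output (or input) file path.
#' @return `wkelm_save()` returns `path` invisibly; `wkelm_load()`
#'   returns the restored `wkelm` model.
#' @export
wkelm_save <- function(model, path) {
  stopifnot(inherits(model, "wkelm"))
  payload <- list(
    format = "wkelm-model",
    version = 1L,
    variant = model$variant,
    kernel = if (!is.null(model$kernel)) unclass(model$kernel),
    E = model$E,
    n_hidden = model$n_hidden,
    activation = model$activation,
    seed = model$seed,
    n_train = model$n_train,
    feature_names = model$feature_names,
    label_map = model$label_map,
    standardizer = model$standardizer,
    output_weights = model$output_weights,
    reference_points = model$reference_points,
    input_weights = model$input_weights,
    biases = model$biases,
    center_index = model$center_index
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname wkelm_save
#' @export
wkelm_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "wkelm-model") {
    stop("not a wkelm model file: ", path, call. = FALSE)
  }
  model <- list(
    variant = p$variant,
    kernel = if (!is.null(p$kernel)) {
      kernel_spec(p$kernel$family, w = p$kernel$w, x = p$kernel$x,
                  y = p$kernel$y, degree = p$kernel$degree,
                  gamma = p$kernel$gamma, form = p$kernel$form)
    },
    E = p$E,
    n_hidden = p$n_hidden,
    activation = p$activation,
    seed = p$seed,
    n_train = p$n_train,
    feature_names = p$feature_names,
    label_map = as.list(p$label_map),
    standardizer = list(mean = unlist(p$standardizer$mean),
                        sd = unlist(p$standardizer$sd)),
    output_weights = as.numeric(p$output_weights)
  )
  if (!is.null(p$reference_points)) {
    model$reference_points <- as.matrix(p$reference_points)
  }
  if (!is.null(p$input_weights)) {
    model$input_weights <- as.matrix(p$input_weights)
    model$biases <- as.numeric(p$biases)
  }
  if (!is.null(p$center_index)) model$center_index <- as.integer(p$center_index)
  class(model) <- "wkelm"
  model
}

#' Save an evaluation report
#'
#' Writes the per-split and aggregate statistics of a [run_protocol()]
#' result as JSON, and optionally the ROC points of each split as a
#' two-column tab-separated file.
#'
#' @param eval A [run_protocol()] result.
#' @param path JSON output path.
#' @param roc_path Optional path for a TSV of ROC points (columns:
#'   repeat_id, fold, fpr, tpr).
#' @return `path`, invisibly.
#' @export
eval_save <- function(eval, path, roc_path = NULL) {
  stopifnot(inherits(eval, "wkelm_eval"))
  payload <- list(
    format = "wkelm-eval", version = 1L,
    positive = eval$positive,
    per_split = eval$summary,
    aggregate = eval$aggregate
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "rows", pretty = TRUE)
  if (!is.null(roc_path)) {
    roc <- purrr::map_dfr(eval$reports, function(r) {
      dplyr::mutate(r$roc, repeat_id = r$repeat_id, fold = r$fold,
                    .before = 1)
    })
    readr::write_tsv(roc, roc_path, progress = FALSE)
  }
  invisible(path)
}
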