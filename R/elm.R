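#' Fit a (wavelet-)kernel Extreme Learning Machine classifier
#'
#' Trains a two-class ELM in closed form.  Three variants are available:
#'
#' * `full_kernel`: the kernel-trick ELM.  With kernel matrix
#'   `D = kernel_matrix(X, X)` the output weights `S` solve the
#'   regularised system `(I/E + D) S = C`, where `C` is the +/-1 label
#'   vector and `E` the regulation coefficient; every training sample is
#'   a reference point, so no hidden-neuron count is involved.
#' * `center_subset`: an explicit kernel-neuron hidden layer.  `K =
#'   n_hidden` centers are chosen by a seeded shuffle of the training
#'   rows, the hidden output matrix is `A[i, k] = b(x_i, c_k)`, and
#'   `S = A' (I/E + A A')^{-1} C`.  This is the variant whose
#'   neuron-count a genetic-algorithm search can tune.
#' * `random_feature`: the classic ELM baseline.  Input weights and
#'   biases are drawn uniform(-1, 1) under the seed, the hidden matrix
#'   is `H[i, k] = f(l_k . x_i + b_k)` for the chosen activation, and
#'   the output weights are the Moore-Penrose least-squares solution
#'   `pinv(H) C`.
#'
#' Features are z-scored with statistics fitted on the training rows
#' only (voice features span orders of magnitude, Hz against ratios).
#' Labels are mapped to +1 (positive class) and -1; the decision
#' threshold is 0 with ties going to the positive class.
#'
#' @param data A data frame of training rows.
#' @param outcome Name of the binary label column (default `"status"`).
#' @param features Character vector of feature columns; default all
#'   numeric columns except the outcome.
#' @param kernel A [kernel_spec()] (kernel variants).  The default
#'   wavelet parameters (w = 1, x = 8, y = 16) keep the cosine factor
#'   slowly varying relative to typical distances between z-scored
#'   voice-feature vectors, so that nearby training samples contribute
#'   with a consistent sign.
#' @param variant `"full_kernel"`, `"center_subset"` or
#'   `"random_feature"`.
#' @param E Regulation (ridge) coefficient, > 0.  Default 1.
#' @param n_hidden Hidden-neuron / center count `K` (center_subset and
#'   random_feature).  Must not exceed the number of training rows for
#'   center_subset.
#' @param activation Activation for random_feature: `"sigmoid"`
#'   (logistic), `"tangent_sigmoid"` (tanh), `"triangular_basis"`
#'   (`max(0, 1 - |z|)`), `"radial_basis"` (`exp(-z^2)`) or
#'   `"hard_limit"` (step at 0).
#' @param positive The label value of the positive (diseased) class;
#'   default: the `positive_class` attribute of `data` if present, else
#'   1 for 0/1 labels, else the larger sorted unique value.
#' @param seed Integer seed for center selection / random weights.
#' @return An object of class `wkelm`.
#' @examples
#' d <- simulate_parkinsons(n_samples = 60, effect_size = 2, seed = 1)
#' fit <- wkelm(d, kernel = kernel_spec("wavelet", w = 2, x = 2, y = 8))
#' mean(predict(fit, d) == d$status)
#' @export
wkelm <- function(data, outcome = "status", features = NULL,
                  kernel = kernel_spec("wavelet", w = 1, x = 8, y = 16),
                  variant = c("full_kernel", "center_subset", "random_feature"),
                  E = 1, n_hidden = NULL,
                  activation = c("sigmoid", "tangent_sigmoid",
                                 "triangular_basis", "radial_basis",
                                 "hard_limit"),
                  positive = NULL, seed = 1L) {
  variant <- match.arg(variant)
  activation <- match.arg(activation)
  if (!is.numeric(E) || length(E) != 1 || E <= 0) {
    stop("regulation coefficient E must be a single value > 0", call. = FALSE)
  }
  dm <- dataset_matrix(data, outcome = outcome, features = features)
  X <- dm$X
  labels <- dm$labels
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training rows", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (is.null(positive)) positive <- attr(data, "positive_class")
  if (is.null(positive)) positive <- classes[length(classes)]
  if (!positive %in% classes) {
    stop("positive class '", positive, "' not present in labels",
         call. = FALSE)
  }
  negative <- setdiff(classes, positive)
  C <- ifelse(labels == positive, 1, -1)

  std <- standardize_fit(X)
  Z <- standardize_apply(std, X)

  if (variant != "random_feature" && !inherits(kernel, "kernel_spec")) {
    stop("kernel must be a kernel_spec object", call. = FALSE)
  }
  if (variant %in% c("center_subset", "random_feature")) {
    if (is.null(n_hidden)) {
      n_hidden <- if (variant == "center_subset") n else min(n, 50L)
    }
    if (n_hidden < 1) stop("n_hidden must be >= 1", call. = FALSE)
    if (variant == "center_subset" && n_hidden > n) {
      stop("n_hidden (", n_hidden, ") exceeds the number of training rows (",
           n, ")", call. = FALSE)
    }
  }

  fitted <- switch(variant,
    full_kernel = {
      D <- kernel_matrix(Z, Z, kernel)
      S <- solve_regularized(diag(n) / E + D, C)
      list(reference_points = Z, output_weights = as.numeric(S))
    },
    center_subset = {
      idx <- withr::with_seed(seed, sample.int(n)[seq_len(n_hidden)])
      centers <- Z[idx, , drop = FALSE]
      A <- kernel_matrix(Z, centers, kernel)
      inner <- solve_regularized(diag(n) / E + A %*% t(A), C)
      list(reference_points = centers,
           output_weights = as.numeric(t(A) %*% inner),
           center_index = idx)
    },
    random_feature = {
      p <- ncol(Z)
      wb <- withr::with_seed(seed, {
        list(l = matrix(stats::runif(p * n_hidden, -1, 1), p, n_hidden),
             b = stats::runif(n_hidden, -1, 1))
      })
      H <- activation_fun(activation)(sweep(Z %*% wb$l, 2, wb$b, "+"))
      beta <- MASS::ginv(H) %*% C
      list(input_weights = wb$l, biases = wb$b,
           output_weights = as.numeric(beta))
    }
  )

  structure(
    c(fitted,
      list(variant = variant, kernel = kernel, E = E,
           n_hidden = if (variant == "full_kernel") NULL else n_hidden,
           activation = if (variant == "random_feature") activation else NULL,
           standardizer = std, feature_names = dm$features,
           label_map = list(positive = positive, negative = negative),
           n_train = n, seed = as.integer(seed))),
    class = "wkelm"
  )
}

activation_fun <- function(name) {
  switch(name,
    sigmoid          = stats::plogis,
    tangent_sigmoid  = tanh,
    triangular_basis = function(z) pmax(0, 1 - abs(z)),
    radial_basis     = function(z) exp(-z^2),
    hard_limit       = function(z) (z >= 0) + 0,
    stop("unknown activation: ", name, call. = FALSE)
  )
}

# Symmetric solve with least-squares (pseudoinverse) fallback; never an
# explicit inverse.  The wavelet kernel need not be PSD, so singular
# systems are a legitimate (if rare) runtime condition.
solve_regularized <- function(M, C, tol = 1e-10) {
  tryCatch(
    solve(M, C, tol = tol),
    error = function(e) {
      warning("regularized system is ill-conditioned; using least-squares ",
              "fallback", call. = FALSE)
      MASS::ginv(M) %*% C
    }
  )
}

#' Real-valued decision scores of a fitted ELM
#'
#' Applies the model's stored standardiser to `data` and evaluates the
#' output function: for kernel variants the kernel vector against the
#' stored reference points times the output weights; for the
#' random-feature variant the weighted hidden activations.  The sign of
#' the score is the predicted class.
#'
#' @param model A fitted [wkelm()] model.
#' @param data A data frame (or numeric matrix) with the model's
#'   feature columns.
#' @return A numeric vector with one score per row.
#' @export
decision_scores <- function(model, data) {
  stopifnot(inherits(model, "wkelm"))
  X <- if (is.matrix(data)) data else {
    missing <- setdiff(model$feature_names, names(data))
    if (length(missing) > 0) {
      stop("data lacks feature columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    as.matrix(data[model$feature_names])
  }
  if (ncol(X) != length(model$standardizer$mean)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  Z <- standardize_apply(model$standardizer, X)
  if (model$variant == "random_feature") {
    H <- activation_fun(model$activation)(
      sweep(Z %*% model$input_weights, 2, model$biases, "+"))
    return(as.numeric(H %*% model$output_weights))
  }
  K <- kernel_matrix(Z, model$reference_points, model$kernel)
  as.numeric(K %*% model$output_weights)
}

#' Predict class labels from a fitted ELM
#'
#' @param object A fitted [wkelm()] model.
#' @param newdata A data frame or matrix of rows to classify.
#' @param type `"class"` (default) for labels on the original coding, or
#'   `"score"` for the raw decision scores.
#' @param ... Unused.
#' @return A vector of predicted labels (scores >= 0 map to the
#'   positive class) or of scores.
#' @export
predict.wkelm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  u <- decision_scores(object, newdata)
  if (type == "score") return(u)
  ifelse(u >= 0, object$label_map$positive, object$label_map$negative)
}

#' @export
print.wkelm <- function(x, ...) {
  cat(sprintf("<wkelm> %s ELM, %d training rows, %d features, E = %g\n",
              x$variant, x$n_train, length(x$feature_names), x$E))
  if (x$variant != "random_feature") print(x$kernel)
  if (!is.null(x$n_hidden)) cat("hidden neurons:", x$n_hidden, "\n")
  invisible(x)
}

#' Tidy the output weights of a fitted ELM
#'
#' @param x A fitted [wkelm()] model.
#' @param ... Unused.
#' @return A tibble with one row per reference point / hidden neuron and
#'   its output weight.
#' @method tidy wkelm
#' @export
tidy.wkelm <- function(x, ...) {
  tibble::tibble(
    term = seq_along(x$output_weights),
    weight = x$output_weights
  )
}

#' One-row model summary of a fitted ELM
#'
#' @param x A fitted [wkelm()] model.
#' @param ... Unused.
#' @return A one-row tibble: variant, kernel family and parameters,
#'   regulation coefficient, sizes.
#' @method glance wkelm
#' @export
glance.wkelm <- function(x, ...) {
  model <- x
  is_wavelet <- model$variant != "random_feature" &&
    model$kernel$family == "wavelet"
  tibble::tibble(
    variant = model$variant,
    kernel = if (model$variant == "random_feature") model$activation
             else model$kernel$family,
    w = if (is_wavelet) model$kernel$w else NA_real_,
    x = if (is_wavelet) model$kernel$x else NA_real_,
    y = if (is_wavelet) model$kernel$y else NA_real_,
    E = model$E,
    n_hidden = if (is.null(model$n_hidden)) NA_integer_
               else as.integer(model$n_hidden),
    n_train = model$n_train,
    n_features = length(model$feature_names)
  )
}
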