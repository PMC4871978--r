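#' Canonical UCI Parkinsons voice feature names
#'
#' The 22 biomedical voice-measurement attributes of the UCI Parkinsons
#' dysphonia table, in file order: fundamental-frequency statistics
#' (Fo/Fhi/Flo), the jitter family (frequency perturbation), the shimmer
#' family (amplitude perturbation), noise-to-harmonics measures
#' (NHR/HNR) and nonlinear dynamical measures (RPDE, DFA, spread1,
#' spread2, D2, PPE).
#'
#' @format A character vector of length 22.
#' @export
parkinsons_features <- c(
  "MDVP:Fo(Hz)", "MDVP:Fhi(Hz)", "MDVP:Flo(Hz)",
  "MDVP:Jitter(%)", "MDVP:Jitter(Abs)", "MDVP:RAP", "MDVP:PPQ",
  "Jitter:DDP",
  "MDVP:Shimmer", "MDVP:Shimmer(dB)", "Shimmer:APQ3", "Shimmer:APQ5",
  "MDVP:APQ", "Shimmer:DDA",
  "NHR", "HNR",
  "RPDE", "DFA", "spread1", "spread2", "D2", "PPE"
)

#' Read a UCI-Parkinsons-dialect voice CSV
#'
#' Reads a comma-separated table with a header row, at most one
#' non-numeric identifier column, a binary `status` column, and numeric
#' feature columns.  Missing cells are a hard error (the canonical file
#' has none); no imputation is ever performed.
#'
#' Note on polarity: in the public UCI file `status = 1` marks a
#' Parkinson (PD) recording and `status = 0` a healthy one, and that is
#' the default here.  Some secondary descriptions state the opposite;
#' use `positive_label_value` to override if your file differs.
#'
#' @param path Path to a CSV file.
#' @param positive_label_value The `status` value meaning PD
#'   (the positive/diseased class). Default `1`.
#' @return A tibble with the identifier column (if any), the feature
#'   columns in file order and `status`; attributes `positive_class`,
#'   `id_column` and `feature_names` record the schema.
#' @export
read_uci_parkinsons <- function(path, positive_label_value = 1) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"status" %in% names(df)) {
    stop("file ", path, " has no 'status' column", call. = FALSE)
  }
  other <- setdiff(names(df), "status")
  non_num <- other[!vapply(df[other], is.numeric, logical(1))]
  if (length(non_num) > 1) {
    stop("multiple non-numeric columns (", paste(non_num, collapse = ", "),
         "); expected at most one identifier column", call. = FALSE)
  }
  id_col <- if (length(non_num) == 1) non_num else NULL
  feat_cols <- setdiff(other, id_col)
  for (cn in feat_cols) {
    bad <- which(is.na(df[[cn]]))
    if (length(bad) > 0) {
      stop("missing or non-numeric value in column '", cn, "', row ",
           bad[1], call. = FALSE)
    }
  }
  st <- df$status
  if (anyNA(st) || length(setdiff(unique(st), unique(st)[1:2])) > 0 ||
      length(unique(st)) > 2) {
    stop("'status' column is not binary", call. = FALSE)
  }
  if (!positive_label_value %in% st) {
    warning("positive label value ", positive_label_value,
            " does not occur in 'status'")
  }
  attr(df, "positive_class") <- positive_label_value
  attr(df, "id_column") <- id_col
  attr(df, "feature_names") <- feat_cols
  df
}

#' Write a voice-feature table as CSV
#'
#' Plain `readr::write_csv()` with full-precision doubles so that a
#' write/read round trip reproduces the table exactly.
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_voice_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Fit per-feature standardisation statistics
#'
#' Computes the z-score statistics (mean, sd) of each column from
#' training rows only.  Constant columns get sd = 1 so that they map to
#' zero rather than dividing by zero.
#'
#' @param X A numeric matrix or data frame of training rows (>= 2 rows).
#' @return A list with numeric vectors `mean` and `sd`.
#' @export
standardize_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training rows", call. = FALSE)
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

#' Apply standardisation statistics
#'
#' @param stats A list from [standardize_fit()].
#' @param X A matrix or data frame with the same columns as the
#'   training matrix.
#' @return The z-scored matrix.
#' @export
standardize_apply <- function(stats, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty matrix", call. = FALSE)
  if (ncol(X) != length(stats$mean)) {
    stop("matrix has ", ncol(X), " columns but standardizer expects ",
         length(stats$mean), call. = FALSE)
  }
  sweep(sweep(X, 2, stats$mean, "-"), 2, stats$sd, "/")
}

# Correlated standard-normal latent block: one shared factor per block.
latent_block <- function(n, k, rho) {
  shared <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * k), n, k)
  sqrt(rho) * shared + sqrt(1 - rho) * eps
}

#' Simulate a two-class dysphonia feature table
#'
#' Generates a synthetic stand-in for the UCI Parkinsons voice table:
#' 22 positive-valued, heterogeneous-scale features following the
#' canonical schema — a fundamental-frequency trio (log-normal around
#' 100–250 Hz with `Flo <= Fo <= Fhi` by construction), a correlated
#' jitter family on the percent scale, a correlated shimmer family (dB
#' and ratio scales), NHR/HNR with HNR decreasing in NHR, and the
#' nonlinear measures (RPDE, DFA, spread1, spread2, D2, PPE) on their
#' natural scales.  The PD class is shifted by `effect_size` latent
#' standard deviations on the jitter, shimmer and PPE features; jitter
#' and shimmer families share a within-block correlation.
#'
#' @param n_samples Number of recordings (rows); >= 4.
#' @param prevalence Fraction of PD rows in (0, 1); the PD count is
#'   `round(prevalence * n_samples)`.
#' @param effect_size Standardised latent mean shift between classes on
#'   the jitter/shimmer/PPE subset; 0 means no class signal.
#' @param correlation Shared within-block correlation among the jitter
#'   and among the shimmer features, in \[0, 1).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with a `name` identifier column, the 22 features of
#'   [parkinsons_features] and a binary `status` column (1 = PD).
#' @examples
#' d <- simulate_parkinsons(n_samples = 40, seed = 1)
#' table(d$status)
#' @export
simulate_parkinsons <- function(n_samples = 192, prevalence = 0.75,
                                effect_size = 1.5, correlation = 0.6,
                                seed = 1) {
  if (n_samples < 4) stop("n_samples must be >= 4", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be in (0, 1)", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (correlation < 0 || correlation >= 1) {
    stop("correlation must be in [0, 1)", call. = FALSE)
  }
  n_pd <- round(prevalence * n_samples)
  if (n_pd < 2 || n_samples - n_pd < 2) {
    stop("each class needs at least 2 rows; adjust n_samples/prevalence",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    status <- sample(c(rep(1L, n_pd), rep(0L, n_samples - n_pd)))
    shift <- effect_size * status  # latent-scale shift for the PD class

    # fundamental frequency trio (Hz); multipliers keep Flo <= Fo <= Fhi
    fo <- exp(log(150) + 0.25 * stats::rnorm(n_samples))
    up <- abs(stats::rnorm(n_samples, 0.15, 0.05))
    dn <- pmin(abs(stats::rnorm(n_samples, 0.12, 0.04)), 0.9)
    fhi <- fo * (1 + up)
    flo <- fo * (1 - dn)

    zj <- latent_block(n_samples, 5, correlation) + shift
    jitter_pct <- exp(-5.0 + 0.45 * zj[, 1])
    jitter_abs <- exp(-10.1 + 0.45 * zj[, 2])
    rap <- exp(-5.8 + 0.5 * zj[, 3])
    ppq <- exp(-5.7 + 0.5 * zj[, 4])
    ddp <- 3 * rap * exp(0.05 * zj[, 5])

    zs <- latent_block(n_samples, 6, correlation) + shift
    shimmer <- exp(-3.5 + 0.4 * zs[, 1])
    shimmer_db <- exp(-1.2 + 0.4 * zs[, 2])
    apq3 <- exp(-4.2 + 0.45 * zs[, 3])
    apq5 <- exp(-4.0 + 0.45 * zs[, 4])
    apq <- exp(-3.8 + 0.45 * zs[, 5])
    dda <- 3 * apq3 * exp(0.05 * zs[, 6])

    nhr <- exp(-3.5 + 0.8 * stats::rnorm(n_samples))
    hnr <- 10 - 4 * log(nhr) + stats::rnorm(n_samples, 0, 1)

    rpde <- stats::plogis(0.2 + 0.6 * stats::rnorm(n_samples))
    dfa <- 0.72 + 0.04 * stats::rnorm(n_samples)
    spread1 <- -6 + 1.0 * stats::rnorm(n_samples)
    spread2 <- 0.23 + 0.07 * stats::rnorm(n_samples)
    d2 <- 2.4 + 0.35 * stats::rnorm(n_samples)
    ppe <- stats::plogis(-1.5 + 0.5 * (stats::rnorm(n_samples) + shift))

    out <- tibble::tibble(
      name = sprintf("synth_R%03d", seq_len(n_samples)),
      `MDVP:Fo(Hz)` = fo, `MDVP:Fhi(Hz)` = fhi, `MDVP:Flo(Hz)` = flo,
      `MDVP:Jitter(%)` = jitter_pct, `MDVP:Jitter(Abs)` = jitter_abs,
      `MDVP:RAP` = rap, `MDVP:PPQ` = ppq, `Jitter:DDP` = ddp,
      `MDVP:Shimmer` = shimmer, `MDVP:Shimmer(dB)` = shimmer_db,
      `Shimmer:APQ3` = apq3, `Shimmer:APQ5` = apq5, `MDVP:APQ` = apq,
      `Shimmer:DDA` = dda,
      NHR = nhr, HNR = hnr,
      RPDE = rpde, DFA = dfa, spread1 = spread1, spread2 = spread2,
      D2 = d2, PPE = ppe,
      status = status
    )
    attr(out, "positive_class") <- 1L
    attr(out, "id_column") <- "name"
    attr(out, "feature_names") <- parkinsons_features
    out
  })
}

# Extract the numeric feature matrix and labels from a data frame.
# Feature columns default to every numeric column except the outcome.
dataset_matrix <- function(data, outcome = "status", features = NULL) {
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  if (is.null(features)) {
    cand <- setdiff(names(data), outcome)
    features <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  if (length(features) < 1) stop("no numeric feature columns", call. = FALSE)
  X <- as.matrix(data[features])
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  labels <- data[[outcome]]
  u <- unique(labels)
  if (length(u) > 2) stop("outcome has more than two classes", call. = FALSE)
  list(X = X, labels = labels, features = features)
}
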