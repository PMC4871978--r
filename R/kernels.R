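#' Kernel specification
#'
#' Describes one of the kernel families used by the kernel ELM: the
#' three-parameter wavelet kernel that is the package's workhorse, or one
#' of the classical comparison kernels (linear, polynomial, Gaussian,
#' exponential).
#'
#' The wavelet kernel is the translation-invariant family
#' \deqn{b(r, g) = \cos\!\left(\frac{w\,\lVert r-g\rVert}{x}\right)
#'   \exp\!\left(-\frac{\lVert r-g\rVert^2}{y}\right)}
#' with an oscillation parameter `w`, an oscillation scale `x` and a
#' Gaussian width `y` (all dimensionless; `y > 0`).  When the parameters
#' come from chromosome decoding (see [decode_chromosome()]) each lies in
#' 1..16.  An alternative separable form, the per-dimension product
#' \eqn{\prod_d \cos(w (r_d-g_d)/x) \exp(-(r_d-g_d)^2/y)}, is available
#' via `form = "product"`; the norm-based form is the default everywhere.
#'
#' The norm-based wavelet kernel is *not* guaranteed positive
#' semidefinite; the solvers in [wkelm()] therefore never assume
#' definiteness and fall back to least squares when a system is singular.
#'
#' @param family One of `"wavelet"`, `"linear"`, `"polynomial"`,
#'   `"gaussian"`, `"exponential"`.
#' @param w,x,y Wavelet-kernel parameters (ignored by other families).
#' @param degree Polynomial degree (polynomial family only).
#' @param gamma Positive rate parameter (gaussian/exponential families).
#' @param form `"norm"` (default) or `"product"`; wavelet family only.
#' @return An object of class `kernel_spec`.
#' @examples
#' ks <- kernel_spec("wavelet", w = 15, x = 3, y = 10)
#' wavelet_kernel(c(1, 0), c(0, 0), ks)
#' @export
kernel_spec <- function(family = c("wavelet", "linear", "polynomial",
                                   "gaussian", "exponential"),
                        w = 1, x = 1, y = 1, degree = 2, gamma = 1,
                        form = c("norm", "product")) {
  family <- match.arg(family)
  form <- match.arg(form)
  if (family == "wavelet") {
    if (!is.numeric(y) || length(y) != 1 || y <= 0) {
      stop("wavelet kernel requires a single width parameter y > 0",
           call. = FALSE)
    }
    if (!is.numeric(w) || !is.numeric(x) || length(w) != 1 || length(x) != 1) {
      stop("wavelet kernel parameters w and x must be single numbers",
           call. = FALSE)
    }
    if (x == 0) stop("wavelet oscillation scale x must be nonzero", call. = FALSE)
  }
  if (family == "polynomial" &&
      (!is.numeric(degree) || length(degree) != 1 || degree < 1 ||
       degree != round(degree))) {
    stop("polynomial kernel requires an integer degree >= 1", call. = FALSE)
  }
  if (family %in% c("gaussian", "exponential") &&
      (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)) {
    stop(family, " kernel requires gamma > 0", call. = FALSE)
  }
  structure(
    list(family = family, w = w, x = x, y = y, degree = degree,
         gamma = gamma, form = form),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  pars <- switch(x$family,
    wavelet     = sprintf("w = %g, x = %g, y = %g%s", x$w, x$x, x$y,
                          if (x$form == "product") " (product form)" else ""),
    polynomial  = sprintf("degree = %d", x$degree),
    gaussian    = ,
    exponential = sprintf("gamma = %g", x$gamma),
    linear      = ""
  )
  cat(sprintf("<kernel_spec> %s kernel%s\n", x$family,
              if (nzchar(pars)) paste0(" (", pars, ")") else ""))
  invisible(x)
}

check_kernel_vectors <- function(r, g) {
  r <- as.numeric(r)
  g <- as.numeric(g)
  if (length(r) != length(g)) {
    stop("feature vectors have different dimensions (", length(r), " vs ",
         length(g), ")", call. = FALSE)
  }
  list(r = r, g = g)
}

#' Wavelet kernel between two feature vectors
#'
#' Evaluates the wavelet kernel
#' \eqn{\cos(w\,d/x)\,\exp(-d^2/y)} with \eqn{d = \lVert r-g\rVert}
#' (or its per-dimension product form, see [kernel_spec()]).  The value
#' always lies in \[-1, 1\] and equals 1 when `r == g`.
#'
#' @param r,g Numeric feature vectors of equal length.
#' @param spec A wavelet [kernel_spec()].
#' @return A single kernel value.
#' @export
wavelet_kernel <- function(r, g, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$family != "wavelet") {
    stop("spec must describe a wavelet kernel", call. = FALSE)
  }
  if (spec$y <= 0) stop("wavelet width y must be > 0", call. = FALSE)
  v <- check_kernel_vectors(r, g)
  if (spec$form == "product") {
    dd <- v$r - v$g
    return(prod(cos(spec$w * dd / spec$x) * exp(-dd^2 / spec$y)))
  }
  d <- sqrt(sum((v$r - v$g)^2))
  cos(spec$w * d / spec$x) * exp(-d^2 / spec$y)
}

#' Kernel value for any supported family
#'
#' Dispatches on `spec$family`: linear is the dot product, polynomial is
#' `(dot + 1)^degree`, gaussian is `exp(-gamma * d^2)`, exponential is
#' `exp(-gamma * d)`, wavelet is [wavelet_kernel()].
#'
#' @inheritParams wavelet_kernel
#' @param spec A [kernel_spec()].
#' @return A single kernel value.
#' @export
kernel_value <- function(r, g, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  v <- check_kernel_vectors(r, g)
  switch(spec$family,
    wavelet     = wavelet_kernel(v$r, v$g, spec),
    linear      = sum(v$r * v$g),
    polynomial  = (sum(v$r * v$g) + 1)^spec$degree,
    gaussian    = exp(-spec$gamma * sum((v$r - v$g)^2)),
    exponential = exp(-spec$gamma * sqrt(sum((v$r - v$g)^2))),
    stop("unknown kernel family: ", spec$family, call. = FALSE)
  )
}

#' Kernel matrix between two sample matrices
#'
#' Returns the `nrow(X1) x nrow(X2)` matrix of pairwise kernel values,
#' computed with vectorised linear algebra (no explicit double loop).
#' For translation-invariant families (wavelet, gaussian, exponential)
#' the diagonal of `kernel_matrix(X, X, spec)` is all ones.
#'
#' @param X1,X2 Numeric matrices with the same number of columns; rows
#'   are samples.
#' @param spec A [kernel_spec()].
#' @return A numeric matrix of kernel values.
#' @export
kernel_matrix <- function(X1, X2, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) {
    stop("feature dimensions differ (", ncol(X1), " vs ", ncol(X2), ")",
         call. = FALSE)
  }
  cross <- X1 %*% t(X2)
  if (spec$family == "linear") return(cross)
  if (spec$family == "polynomial") return((cross + 1)^spec$degree)
  if (spec$family == "wavelet" && spec$form == "product") {
    K <- matrix(1, nrow(X1), nrow(X2))
    for (j in seq_len(ncol(X1))) {
      dd <- outer(X1[, j], X2[, j], "-")
      K <- K * cos(spec$w * dd / spec$x) * exp(-dd^2 / spec$y)
    }
    return(K)
  }
  # squared distances via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2ab
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * cross
  d2 <- pmax(d2, 0)
  if (identical(X1, X2)) {
    # exact symmetry and zero self-distance despite cancellation error
    d2 <- (d2 + t(d2)) / 2
    diag(d2) <- 0
  }
  switch(spec$family,
    wavelet     = cos(spec$w * sqrt(d2) / spec$x) * exp(-d2 / spec$y),
    gaussian    = exp(-spec$gamma * d2),
    exponential = exp(-spec$gamma * sqrt(d2)),
    stop("unknown kernel family: ", spec$family, call. = FALSE)
  )
}
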