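# Small synthetic problems used across the suite.

# Two well-separated Gaussian clusters in `p` dimensions.
make_clusters <- function(n = 40, p = 4, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    half <- n %/% 2
    X <- rbind(
      matrix(stats::rnorm(half * p), half, p),
      matrix(stats::rnorm((n - half) * p, mean = sep), n - half, p)
    )
    df <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
    names(df) <- paste0("f", seq_len(p))
    df$status <- c(rep(0L, half), rep(1L, n - half))
    df[sample(n), ]
  })
}

# Two concentric 2-D rings: only a narrow kernel width separates them.
make_rings <- function(n = 120, r_inner = 1, r_outer = 2, noise = 0.12,
                       seed = 1) {
  withr::with_seed(seed, {
    half <- n %/% 2
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- c(stats::rnorm(half, r_inner, noise),
             stats::rnorm(n - half, r_outer, noise))
    tibble::tibble(
      f1 = rad * cos(ang),
      f2 = rad * sin(ang),
      status = c(rep(0L, half), rep(1L, n - half))
    )
  })
}

# Feature-label table with no class signal at all.
make_null_data <- function(n = 100, p = 5, prevalence = 0.5, seed = 1) {
  withr::with_seed(seed, {
    df <- tibble::as_tibble(as.data.frame(matrix(stats::rnorm(n * p), n, p)),
                            .name_repair = "minimal")
    names(df) <- paste0("f", seq_len(p))
    df$status <- as.integer(seq_len(n) <= round(prevalence * n))
    df[sample(n), ]
  })
}

random_chromosome <- function() sample(0:1, 20, replace = TRUE)
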