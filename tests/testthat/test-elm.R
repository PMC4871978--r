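test_that("full_kernel output weights satisfy the defining linear system", {
  d <- make_clusters(n = 30, p = 4, sep = 3, seed = 2)
  for (E in c(0.1, 1, 100)) {
    fit <- wkelm(d, E = E)
    Z <- fit$reference_points
    D <- kernel_matrix(Z, Z, fit$kernel)
    C <- ifelse(d$status == fit$label_map$positive, 1, -1)
    resid <- (diag(nrow(Z)) / E + D) %*% fit$output_weights - C
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("full_kernel with a linear kernel reproduces dual-form ridge regression", {
  withr::with_seed(9, {
    X <- matrix(rnorm(20 * 4), 20, 4)
    y <- sample(c(0L, 1L), 20, replace = TRUE)
    y[1:2] <- c(0L, 1L)  # both classes present
    d <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
    names(d) <- paste0("f", 1:4)
    d$status <- y
    fit <- wkelm(d, kernel = kernel_spec("linear"), E = 1)
    # independent closed-form dual ridge oracle on the z-scored features
    mu <- colMeans(X); sdev <- apply(X, 2, sd)
    A <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
    C <- ifelse(y == 1, 1, -1)
    w_ridge <- t(A) %*% solve(diag(20) / 1 + A %*% t(A), C)
    Xnew <- matrix(rnorm(6 * 4), 6, 4)
    dn <- tibble::as_tibble(as.data.frame(Xnew), .name_repair = "minimal")
    names(dn) <- paste0("f", 1:4)
    oracle <- sweep(sweep(Xnew, 2, mu, "-"), 2, sdev, "/") %*% w_ridge
    expect_lt(max(abs(decision_scores(fit, dn) - as.numeric(oracle))), 1e-8)
  })
})

test_that("center_subset weights match the normal-equations closed form", {
  # push-through identity oracle: A'(I/E + AA')^{-1}C = (I/E + A'A)^{-1}A'C
  d <- make_clusters(n = 25, p = 3, sep = 2, seed = 4)
  fit <- wkelm(d, variant = "center_subset", n_hidden = 10, E = 2, seed = 5)
  Zfull <- standardize_apply(fit$standardizer,
                             as.matrix(d[fit$feature_names]))
  A <- kernel_matrix(Zfull, fit$reference_points, fit$kernel)
  C <- ifelse(d$status == fit$label_map$positive, 1, -1)
  oracle <- solve(diag(10) / 2 + t(A) %*% A, t(A) %*% C)
  expect_lt(max(abs(fit$output_weights - as.numeric(oracle))), 1e-8)
})

test_that("center_subset using every training row classifies a separable toy like full_kernel", {
  d <- make_clusters(n = 30, p = 3, sep = 6, seed = 6)
  full <- wkelm(d, E = 100)
  cs <- wkelm(d, variant = "center_subset", n_hidden = nrow(d), E = 100)
  expect_identical(predict(cs, d), predict(full, d))
  expect_identical(predict(full, d), d$status)
})

test_that("random_feature ELM with K = N distinct samples interpolates the training labels", {
  withr::with_seed(12, {
    d <- make_clusters(n = 10, p = 3, sep = 2, seed = 12)
    fit <- wkelm(d, variant = "random_feature", n_hidden = 10,
                 activation = "radial_basis", seed = 3)
    expect_identical(predict(fit, d), d$status)
    # direct least-squares oracle on the same hidden matrix
    Z <- standardize_apply(fit$standardizer, as.matrix(d[fit$feature_names]))
    H <- exp(-(sweep(Z %*% fit$input_weights, 2, fit$biases, "+"))^2)
    C <- ifelse(d$status == fit$label_map$positive, 1, -1)
    beta <- qr.solve(H, C)
    expect_lt(max(abs(H %*% beta - C)), 1e-6)
  })
})

test_that("decision scores separate a linearly separable toy at large E", {
  d <- make_clusters(n = 40, p = 2, sep = 8, seed = 8)
  fit <- wkelm(d, E = 1e6)
  u <- decision_scores(fit, d)
  expect_identical(ifelse(u >= 0, 1L, 0L), d$status)
  # deterministic and shape-stable
  expect_identical(u, decision_scores(fit, d))
  expect_length(decision_scores(fit, d[1, ]), 1)
})

test_that("predict applies the >= 0 threshold with ties to the positive class", {
  d <- make_clusters(n = 20, p = 2, sep = 5, seed = 3)
  fit <- wkelm(d)
  u <- decision_scores(fit, d)
  expect_identical(predict(fit, d),
                   ifelse(u >= 0, fit$label_map$positive,
                          fit$label_map$negative))
  # the threshold rule itself on fabricated scores
  expect_identical(ifelse(c(-0.3, 0, 2.1) >= 0, "P", "N"), c("N", "P", "P"))
})

test_that("4-point toy matches an end-to-end hand linear-algebra oracle", {
  X <- matrix(c(0, 0,
                0, 1,
                3, 3,
                3, 4), 4, 2, byrow = TRUE)
  d <- tibble::tibble(f1 = X[, 1], f2 = X[, 2], status = c(0L, 0L, 1L, 1L))
  spec <- kernel_spec("wavelet", w = 1, x = 1, y = 2)
  fit <- wkelm(d, kernel = spec, E = 100)
  # oracle: explicit standardisation, 4x4 kernel matrix and solve
  mu <- colMeans(X); sdev <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  D <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    dd <- sqrt(sum((Z[i, ] - Z[j, ])^2))
    D[i, j] <- cos(dd) * exp(-dd^2 / 2)
  }
  S <- solve(diag(4) / 100 + D, c(-1, -1, 1, 1))
  u <- D %*% S
  expect_lt(max(abs(decision_scores(fit, d) - as.numeric(u))), 1e-10)
  expect_identical(predict(fit, d), ifelse(as.numeric(u) >= 0, 1L, 0L))
})

test_that("training accuracy is non-decreasing in the regulation coefficient", {
  for (s in 1:5) {
    d <- simulate_parkinsons(n_samples = 80, effect_size = 1, seed = s)
    acc <- vapply(c(0.01, 1, 100, 1e4), function(E) {
      mean(predict(wkelm(d, E = E), d) == d$status)
    }, 0)
    expect_false(is.unsorted(acc))  # ties allowed
  }
})

test_that("swapping the class labels flips every decision score", {
  d <- make_clusters(n = 24, p = 3, sep = 2, seed = 10)
  fit_pos1 <- wkelm(d, positive = 1)
  fit_pos0 <- wkelm(d, positive = 0)
  expect_equal(decision_scores(fit_pos0, d), -decision_scores(fit_pos1, d),
               tolerance = 1e-12)
})

test_that("fit is deterministic given data, kernel and seed", {
  d <- make_clusters(n = 30, p = 4, sep = 2, seed = 14)
  for (v in c("full_kernel", "center_subset", "random_feature")) {
    f1 <- wkelm(d, variant = v, n_hidden = 12, seed = 7)
    f2 <- wkelm(d, variant = v, n_hidden = 12, seed = 7)
    expect_identical(f1$output_weights, f2$output_weights)
  }
})

test_that("fit rejects invalid inputs", {
  d <- make_clusters(n = 20, p = 2, sep = 2, seed = 1)
  d_one <- d; d_one$status <- 1L
  expect_error(wkelm(d_one), "single class")
  expect_error(wkelm(d, E = 0), "E must be")
  expect_error(wkelm(d, variant = "center_subset", n_hidden = 50),
               "exceeds the number of training rows")
  expect_error(decision_scores(wkelm(d), d["f1"]), "lacks feature columns")
})
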