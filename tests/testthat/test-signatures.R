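test_that("cosine similarities equal the direct dot-product formula", {
  set.seed(71)
  a <- matrix(runif(96 * 3), 96, 3)
  b <- matrix(runif(96 * 4), 96, 4)
  cm <- cosine_matrix(a, b)
  for (i in 1:3) for (j in 1:4) {
    expect_equal(cm[i, j],
                 sum(a[, i] * b[, j]) /
                   (sqrt(sum(a[, i]^2)) * sqrt(sum(b[, j]^2))))
  }
  # self-match is 1, orthogonal unit channels are 0
  e1 <- matrix(0, 96, 1); e1[1, 1] <- 1
  e2 <- matrix(0, 96, 1); e2[2, 1] <- 1
  expect_equal(cosine_matrix(e1, e1)[1, 1], 1)
  expect_equal(cosine_matrix(e1, e2)[1, 1], 0)
})

test_that("k=1 on a single-channel matrix recovers the unit signature", {
  V <- matrix(0, 96, 3, dimnames = list(sbs96_channels(),
                                        paste0("s", 1:3)))
  V[5, ] <- c(10, 20, 30)
  fit <- extract_signatures(V, k = 1, n_restarts = 2, seed = 3)
  expect_equal(unname(fit$signatures[5, 1]), 1, tolerance = 1e-6)
  expect_equal(sum(fit$signatures), 1, tolerance = 1e-6)
  expect_equal(unname(fit$exposures[1, ]), c(10, 20, 30), tolerance = 1e-3)
})

test_that("factorization output is valid and deterministic given a seed", {
  S <- make_signature_set(5, k = 2)
  E <- matrix(c(300, 700, 500, 500, 900, 100), 2, 3)
  V <- simulate_sbs96(S, E, seed = 6, model = "poisson")
  f1 <- extract_signatures(V, k = 2, n_restarts = 3, seed = 9)
  f2 <- extract_signatures(V, k = 2, n_restarts = 3, seed = 9)
  expect_identical(f1, f2)
  expect_true(all(f1$signatures >= 0))
  expect_true(all(f1$exposures >= 0))
  expect_equal(unname(colSums(f1$signatures)), c(1, 1), tolerance = 1e-9)
  # exposures cannot attribute more mutations than observed (within slack)
  expect_true(all(colSums(f1$exposures) <= colSums(V) * (1 + 1e-6) + 1e-6))
})

test_that("reconstruction error is monotone non-increasing in k", {
  S <- make_signature_set(5, k = 3)
  E <- matrix(rgamma(3 * 6, 2) * 400, 3, 6)
  V <- simulate_sbs96(S, E, seed = 8, model = "poisson")
  e1 <- extract_signatures(V, 1, n_restarts = 3, seed = 2)$reconstruction_error
  e2 <- extract_signatures(V, 2, n_restarts = 3, seed = 2)$reconstruction_error
  e3 <- extract_signatures(V, 3, n_restarts = 3, seed = 2)$reconstruction_error
  expect_true(e2 <= e1)
  expect_true(e3 <= e2)
})

test_that("degenerate extraction inputs raise errors", {
  V <- matrix(0, 96, 4)
  expect_error(extract_signatures(V, 1), "degenerate")
  V[1, 1] <- 5
  expect_error(extract_signatures(V, 5), "configuration error")
  expect_error(extract_signatures(V, 0), "configuration error")
  expect_error(extract_signatures(V, 1, n_restarts = 0),
               "configuration error")
})

test_that("noiseless exposures are recovered exactly by NNLS refitting", {
  S <- make_signature_set(12, k = 4)
  E <- matrix(c(1000, 0, 200, 300,
                0, 800, 100, 0,
                50, 50, 50, 50), 4, 3)
  V <- S %*% E
  Ehat <- fit_exposures(V, S)
  expect_equal(unname(Ehat), unname(E), tolerance = 1e-6)
  # zero column -> zero exposures
  V0 <- cbind(V, 0)
  expect_equal(unname(fit_exposures(V0, S)[, 4]), rep(0, 4))
  # channel order mismatch is rejected
  S2 <- S; rownames(S2) <- rev(rownames(S2))
  expect_error(fit_exposures(V, S2), "format error")
})

test_that("catalog matching reports the best cosine per signature", {
  S <- make_signature_set(12, k = 4)
  p <- tempfile(fileext = ".tsv")
  write_sbs96_tsv(S, p)
  m <- match_to_catalog(S, p)
  expect_equal(m$best$match, colnames(S))
  expect_equal(m$best$cosine, rep(1, 4), tolerance = 1e-12)
  expect_equal(dim(m$similarity), c(4L, 4L))
})

test_that("rank scan reports errors and stability without auto-selecting", {
  S <- make_signature_set(5, k = 2)
  E <- matrix(rgamma(2 * 8, 2) * 600, 2, 8)
  V <- simulate_sbs96(S, E, seed = 14, model = "poisson")
  sc <- scan_signature_rank(V, ks = 1:2, n_restarts = 3, seed = 4,
                            max_iter = 500)
  expect_equal(sc$k, 1:2)
  expect_true(sc$reconstruction_error[2] <= sc$reconstruction_error[1])
  expect_true(all(sc$stability > 0.8))  # planted ranks refit stably
})
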