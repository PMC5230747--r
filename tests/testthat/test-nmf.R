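test_that("a rank-1 nonnegative matrix is reconstructed almost exactly", {
  silicophys:::withr_seed(1, {
    w <- runif(30)
    h <- runif(80)
  })
  X <- outer(w, h)
  fit <- nmf_fit(X, k = 1, max_iter = 500, tol = 1e-12)
  rel <- sqrt(sum((X - fit$W %*% fit$H)^2) / sum(X^2))
  expect_lt(rel, 1e-6)
})

test_that("negative input is rejected with guidance", {
  expect_error(nmf_fit(matrix(c(1, -1, 2, 3), 2)), "z-score")
})

test_that("the objective is non-increasing and the fit deterministic", {
  silicophys:::withr_seed(4, X <- matrix(rexp(50 * 40), 50))
  fit <- nmf_fit(X, k = 5, max_iter = 100)
  expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
  fit2 <- nmf_fit(X, k = 5, max_iter = 100)
  expect_identical(fit$W, fit2$W)
  fr <- nmf_fit(X, k = 5, seed = 9, init = "random", max_iter = 50)
  fr2 <- nmf_fit(X, k = 5, seed = 9, init = "random", max_iter = 50)
  expect_identical(fr$H, fr2$H)
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(nrow(tidy(fit, "W")), 50 * 5)
})

test_that("planted factors are recovered up to permutation", {
  silicophys:::withr_seed(6, {
    W <- matrix(runif(60 * 4) * (runif(60 * 4) < 0.4), 60, 4)
    H <- matrix(runif(4 * 300), 4, 300)
  })
  X <- gen_planted_nmf(W, H, noise_sd = 0.02, seed = 2)
  fit <- nmf_fit(X, k = 4, max_iter = 500)
  mc <- match_components(fit$H, H)
  expect_true(all(mc$correlation > 0.95))
  expect_setequal(mc$reference, 1:4)
})

test_that("component interpretation reports signed correlations and dominance", {
  H <- rbind(sin(1:200) + 2, rep(1, 200))
  W <- rbind(c(1, 0), c(0, 1), c(1, 0))
  fit <- structure(list(W = W, H = H, k = 2, objective = 1,
                        iterations = 1, converged = TRUE, seed = 1),
                   class = "factorization")
  sigs <- cbind(same = H[1, ], anti = -H[1, ] + 10)
  ci <- interpret_components(fit, sigs, positions = cbind(1:3, 4:6))
  expect_equal(ci$correlations["comp1", "same"], 1)
  expect_equal(ci$correlations["comp1", "anti"], -1)
  expect_equal(ci$dominant$component, c(1L, 2L, 1L))
  expect_equal(ci$dominant$x, 1:3)
})

test_that("component matching is exact on a known permutation", {
  silicophys:::withr_seed(8, H <- matrix(runif(4 * 50), 4))
  perm <- c(3, 1, 4, 2)
  mc <- match_components(H[perm, ], H)
  expect_equal(mc$reference, perm)
  expect_true(all(mc$correlation > 0.999))
})
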