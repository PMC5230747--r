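test_that("order-0 VAR reduces to the mean and sample covariance", {
  silicophys:::withr_seed(1, {
    x <- matrix(rnorm(2 * 4000, mean = c(1, -2)), 2)
  })
  tr <- as_trials(x, n_trials = 8)
  fit <- fit_var(tr, p = 0)
  expect_equal(unname(fit$intercept), rowMeans(x), tolerance = 1e-10)
  xc <- x - rowMeans(x)
  expect_equal(unname(fit$sigma), unname(tcrossprod(xc) / ncol(x)),
               tolerance = 1e-10)
})

test_that("white noise gives near-zero coefficients and order 1", {
  silicophys:::withr_seed(2, x <- matrix(rnorm(2 * 20000), 2))
  tr <- as_trials(x, n_trials = 20)
  fit <- fit_var(tr, p = 2)
  se <- 1 / sqrt(fit$n_obs)
  expect_lt(max(abs(fit$coef)), 4 * se)
  expect_equal(as.integer(select_order(tr, p_range = 1:6)), 1L)
})

test_that("a planted VAR(1) coefficient is recovered", {
  A <- matrix(c(0.9, 0.2, 0, 0.5), 2, 2, byrow = TRUE)
  tr <- gen_var(A, n_trials = 100, trial_length = 1000, seed = 5)
  fit <- fit_var(tr, p = 1)
  expect_equal(unname(fit$coef[1, , ]), unname(A), tolerance = 0.02)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(td$estimate[td$target == "ch1" & td$source == "ch1"],
               fit$coef[1, 1, 1])
})

test_that("rank deficiency is caught with advice to shrink p", {
  silicophys:::withr_seed(3, x <- matrix(rnorm(2 * 400), 2))
  x <- rbind(x, x[1, ]) # duplicated channel makes the lags collinear
  tr <- as_trials(x, n_trials = 4)
  expect_error(fit_var(tr, p = 2), "smaller")
})

test_that("bivariate GC matches the analytic value and is scale-invariant", {
  A <- array(0, c(1, 2, 2))
  A[1, 2, 1] <- 0.9 # y_t = 0.9 x_{t-1} + noise
  tr <- gen_var(A, n_trials = 50, trial_length = 500, seed = 8)
  gxy <- conditional_gc(tr, 1, 2, p = 1)
  expect_equal(gxy, log(1.81), tolerance = 0.05)
  expect_lt(conditional_gc(tr, 2, 1, p = 1), 0.01)

  tr2 <- tr
  tr2[, 1, ] <- tr2[, 1, ] * 37
  tr2[, 2, ] <- tr2[, 2, ] / 11
  expect_equal(conditional_gc(tr2, 1, 2, p = 1), gxy, tolerance = 1e-10)

  expect_error(conditional_gc(tr, 1, 2, conditioning = 1, p = 1), "source")
  expect_error(conditional_gc(tr, 1, 1, p = 1), "differ")
})

test_that("conditioning on the mediator removes chain influence", {
  A <- array(0, c(1, 3, 3))
  A[1, 2, 1] <- 0.8 # x -> y
  A[1, 3, 2] <- 0.8 # y -> z
  tr <- gen_var(A, n_trials = 100, trial_length = 300, seed = 13)
  uncond <- conditional_gc(tr, 1, 3, p = 3)
  cond <- conditional_gc(tr, 1, 3, conditioning = 2, p = 3)
  expect_gt(uncond, 0.1)
  expect_lt(cond, 0.01)
})

test_that("the GC graph recovers planted edges and has no self-edges", {
  A <- array(0, c(1, 3, 3))
  A[1, 2, 1] <- 0.7
  A[1, 3, 2] <- 0.7
  tr <- gen_var(A, n_trials = 40, trial_length = 150, seed = 21)
  g <- gc_graph(tr, p = 2, alpha = 0.05, n_perm = 499, seed = 3)
  expect_equal(nrow(g), 6)
  expect_false(any(g$source == g$target))
  hits <- g$significant
  names(hits) <- paste(g$source, g$target)
  expect_true(hits[["ch1 ch2"]])
  expect_true(hits[["ch2 ch3"]])
  expect_false(hits[["ch2 ch1"]])
  expect_false(hits[["ch1 ch3"]]) # blocked by conditioning on the mediator

  tmp <- withr::local_tempfile(fileext = ".graphml")
  write_gc_graph(g, tmp)
  expect_true(file.size(tmp) > 0)
})
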