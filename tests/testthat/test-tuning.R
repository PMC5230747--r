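test_that("tuning curves are occupancy-normalized and occupancy-invariant", {
  stim <- rep(0:4, times = c(10, 20, 5, 40, 25))
  rate <- rep(2, length(stim))
  tc <- tuning_curve(rate, stim)
  expect_equal(tc$curve$mean_rate, rep(2, 5)) # flat regardless of occupancy
  expect_equal(sum(tc$curve$occupancy), length(stim))

  silicophys:::withr_seed(3, {
    stim2 <- sample(0:5, 400, replace = TRUE)
    rate2 <- stim2 * 1.5 + rnorm(400)
    base <- tuning_curve(rate2, stim2)
    # duplicating every timestep with stimulus 3 leaves curve[3] unchanged
    dup <- c(which(stim2 == 3), seq_along(stim2))
    tc2 <- tuning_curve(rate2[dup], stim2[dup])
    expect_equal(tc2$curve$mean_rate[tc2$curve$stimulus == 3],
                 base$curve$mean_rate[base$curve$stimulus == 3])
  })
  expect_error(tuning_curve(numeric(0), numeric(0)), "empty")
})

test_that("classification separates simple, complex, and untuned shapes", {
  s <- 0:10
  lam_uni <- 8 * exp(-(s - 5)^2 / (2 * 1.5^2)) + 1
  lam_bi <- 5 * exp(-(s - 2)^2 / 0.8) + 5 * exp(-(s - 8)^2 / 0.8) + 1
  mk <- function(lam, noise_seed) {
    silicophys:::withr_seed(noise_seed, {
      stim <- rep(s, each = 400)
      rate <- lam[stim + 1] + rnorm(length(stim), 0, 0.3)
      classify_tuning(tuning_curve(rate, stim))
    })
  }
  expect_equal(mk(lam_uni, 1)$fit$class, "simple")
  expect_equal(mk(lam_bi, 2)$fit$class, "complex")
  flat <- classify_tuning(tuning_curve(rep(3, 44), rep(s, 4)))
  expect_equal(flat$fit$class, "untuned")
  expect_error(classify_tuning(tuning_curve(1:9, rep(1:3, 3))), "4 distinct")
})

test_that("classification is invariant to positive rescaling of rates", {
  pt <- list(a = 8, b = 1, mu = 5, w = 1.5)
  gt <- gen_tuned_spikes(tibble::tibble(a = pt$a, b = pt$b, mu = pt$mu,
                                        w = pt$w),
                         n_timesteps = 20000, seed = 11)
  r <- sliding_rate(gt$spikes, window = 100)[1, ]
  c1 <- classify_tuning(tuning_curve(r, gt$stimulus))
  c2 <- classify_tuning(tuning_curve(3.7 * r, gt$stimulus))
  expect_equal(c1$fit$class, c2$fit$class)
  expect_equal(c1$fit$peak, c2$fit$peak, tolerance = 1e-6)
  expect_equal(c1$fit$eta2, c2$fit$eta2, tolerance = 1e-9)
})

test_that("planted Gaussian tuning is recovered from generated spikes", {
  pt <- list(a = 8, b = 1, mu = 5, w = 1.5)
  gt <- gen_tuned_spikes(tibble::tibble(a = pt$a, b = pt$b, mu = pt$mu,
                                        w = pt$w),
                         n_timesteps = 20000, seed = 4)
  r <- sliding_rate(gt$spikes, window = 100)
  res <- classify_units(r, gt$stimulus)
  expect_equal(res$class, "simple")
  expect_lt(abs(res$peak - pt$mu), 1)
  tc <- classify_tuning(tuning_curve(r[1, ], gt$stimulus))
  expect_s3_class(tidy(tc), "tbl_df")
  expect_equal(glance(tc)$class, "simple")
  expect_s3_class(autoplot(tc), "ggplot")
})
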