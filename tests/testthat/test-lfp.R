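test_that("spatial weights follow the Gaussian closed form", {
  ev <- matrix(1L, 50, 2) # two units, one event per step
  pos <- rbind(c(0, 0), c(500, 0))
  ch <- lfp_channel(ev, center = c(0, 0), sigma = 500, width = 1,
                    positions = pos)
  expect_equal(ch$samples, rep(1 + exp(-0.5), 50)) # weight e^(-1/2) at d = sigma

  # sigma -> infinity limit equals the unweighted population sum
  far <- lfp_channel(ev, center = c(0, 0), sigma = 1e9, width = 1,
                     positions = rbind(c(0, 0), c(12000, 3000)))
  expect_true(all(abs(far$samples - 2) < 1e-6))

  expect_warning(
    lfp_channel(ev, center = c(1e7, 0), sigma = 500, width = 1,
                positions = pos), "4 sigma")
})

test_that("the channel is linear in the event streams", {
  silicophys:::withr_seed(3, {
    e1 <- matrix(rbinom(200, 1, 0.3), 100, 2)
    e2 <- matrix(rbinom(200, 1, 0.3), 100, 2)
  })
  pos <- rbind(c(0, 0), c(300, 100))
  ch <- function(e) lfp_channel(e, c(0, 0), positions = pos)$samples
  expect_equal(ch(e1 + e2), ch(e1) + ch(e2), tolerance = 1e-12)
})

test_that("the moving average is centered with truncated edges", {
  x <- c(rep(0, 10), 8, rep(0, 10))
  y <- silicophys:::moving_average(x, 4)
  expect_equal(sum(y > 0), 4)
  expect_equal(y[9:12], rep(2, 4)) # window [t-1, t+2]
  expect_equal(silicophys:::moving_average(1:3, 4), c(2, 2, 2.5))
})

test_that("Welch spectrum localizes a period-8 impulse train at 0.125", {
  x <- rep(c(1, rep(0, 7)), 1024) # T = 8192
  sp <- welch_periodogram(silicophys:::moving_average(x, 4))
  expect_equal(spectrum_peak(sp), 0.125)
  expect_true(all(sp$power >= 0))
  expect_equal(max(sp$frequency), 0.5)

  # un-detrended constant signal is DC-dominated (residue in the first bin
  # is Hann main-lobe leakage)
  spc <- welch_periodogram(rep(3, 512), detrend = FALSE)
  expect_equal(spectrum_peak(spc, exclude_dc = FALSE), 0)
  expect_gt(spc$power[1], sum(spc$power[-1]))
  expect_lt(sum(spc$power[-(1:2)]), 1e-18)
})

test_that("one-segment Welch agrees with a direct windowed DFT", {
  silicophys:::withr_seed(8, x <- rnorm(256))
  sp <- welch_periodogram(x, nfft = 256, detrend = FALSE)
  w <- 0.5 * (1 - cos(2 * pi * (0:255) / 256))
  ref <- Mod(fft(x * w))^2 / sum(w^2)
  one_sided <- ref[1:129]
  one_sided[2:128] <- one_sided[2:128] + rev(ref)[1:127]
  expect_equal(sp$power, one_sided, tolerance = 1e-10)
  # Parseval consistency: total power equals windowed signal energy
  expect_equal(sum(ref), sum((x * w)^2) * 256 / sum(w^2), tolerance = 1e-8)
})

test_that("switching events count the requested edges", {
  m <- matrix(c(0, 1, 1, 0, 1), ncol = 1)
  expect_equal(as.numeric(switching_events(m, "both")), c(0, 1, 0, 1, 1))
  expect_equal(as.numeric(switching_events(m, "rising")), c(0, 1, 0, 0, 1))
})
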