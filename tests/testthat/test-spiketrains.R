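test_that("rising edges are extracted exactly", {
  m <- matrix(c(0, 0, 1, 1, 0, 1), ncol = 1)
  expect_equal(extract_spikes(m)[[1]], c(3L, 6L))
  expect_equal(extract_spikes(matrix(0, 6, 1))[[1]], integer(0))
  # unit already on at t = 1 does not spike there
  expect_equal(extract_spikes(matrix(c(1, 1, 0, 1), ncol = 1))[[1]], 4L)
  # square wave of period 8 over 8000 steps: 1000 spikes, ISI 8
  sq <- matrix(rep(rep(c(0, 1), each = 4), 1000), ncol = 1)
  ev <- extract_spikes(sq)[[1]]
  expect_length(ev, 1000)
  expect_true(all(diff(ev) == 8))
})

test_that("binning conserves counts and drops partial bins loudly", {
  sp <- structure(list(a = seq(1L, 1000L)), class = "spike_set",
                  n_timesteps = 1000L)
  b <- bin_counts(sp, bin_width = 100)
  expect_true(all(b == 100))
  expect_equal(sum(b), 1000)

  silicophys:::withr_seed(42, {
    ev <- sort(sample.int(950L, 400))
    sp2 <- structure(list(u = ev), class = "spike_set", n_timesteps = 950L)
    expect_message(b2 <- bin_counts(sp2, 100), "partial")
    expect_equal(sum(b2), sum(ev <= 900))
  })
  empty <- structure(list(u = integer(0)), class = "spike_set",
                     n_timesteps = 200L)
  expect_true(all(bin_counts(empty, 100) == 0))
})

test_that("sliding rate equals the trailing-window convolution oracle", {
  sp <- structure(list(u = 10L), class = "spike_set", n_timesteps = 200L)
  r <- sliding_rate(sp, window = 100)[1, ]
  expect_true(all(r[10:109] == 1))
  expect_true(all(r[c(1:9, 110:200)] == 0))

  silicophys:::withr_seed(7, {
    x <- rbinom(500, 1, 0.2)
    spx <- extract_spikes(matrix(c(0, x), ncol = 1))
    got <- sliding_rate(spx, window = 30, n_timesteps = 501)[1, ]
    ref <- stats::filter(tabulate(spx[[1]], 501), rep(1, 30),
                         sides = 1)
    ref[is.na(ref)] <- cumsum(tabulate(spx[[1]], 501))[is.na(ref)]
    expect_equal(as.numeric(got), as.numeric(ref))
  })
})

test_that("z-scoring uses the population convention and maps constants to zero", {
  expect_equal(unclass(zscore(matrix(c(1, 3), 1)))[1, ], c(-1, 1))
  expect_true(all(zscore(matrix(5, 3, 10)) == 0))
  silicophys:::withr_seed(9, {
    m <- matrix(rpois(300, 4), 10)
    z <- zscore(m)
    expect_true(all(abs(rowMeans(z)) < 1e-9))
    expect_true(all(abs(rowMeans(z^2) - 1) < 1e-9))
    expect_equal(unclass(zscore(z)), unclass(z), tolerance = 1e-9)
  })
})
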