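test_that("all fixtures build, self-check, and carry coherent registries", {
  for (nm in c("adder4", "shiftreg8", "counter3_decoder", "microfsm")) {
    fix <- make_fixture(nm)
    expect_s3_class(fix$netlist, "netlist")
    expect_gte(length(fix$registry$behaviors), 1)
    for (bh in fix$registry$behaviors) {
      expect_true(is.function(bh$read_output))
      expect_gte(bh$success_prefix, 1)
    }
  }
  micro <- make_fixture("microfsm")
  expect_gte(length(micro$registry$behaviors), 3)
  expect_true(all(c("CLK0", "CLK1", "RW") %in% micro$registry$signals))
  expect_gte(length(micro$registry$signals), 25)
  expect_true(all(c("control", "pc", "decoder", "adder", "acc", "outreg")
                  %in% names(micro$netlist$modules)))
  streams <- lapply(micro$registry$behaviors, function(b) b$expected_output)
  expect_false(identical(streams[[1]], streams[[2]]))
  expect_false(identical(streams[[2]], streams[[3]]))
})

test_that("counter bits oscillate with their planted periods", {
  fix <- make_fixture("counter3_decoder")
  tr <- run_trace(fix$netlist, two_phase_stimulus(fix$netlist, 64))
  for (k in 0:2) {
    bit <- signal_trace(tr, paste0("BIT", k))
    period <- fix$registry$bit_periods[[paste0("bit", k)]]
    drop_warmup <- bit[(2 * period + 1):length(bit)]
    expect_equal(drop_warmup,
                 rep(drop_warmup[1:period],
                     length.out = length(drop_warmup)))
    expect_equal(sum(abs(diff(bit))), 2 * length(bit) / period,
                 tolerance = 0.1)
  }
})

test_that("the VAR generator is seed-stable, matches its covariance, and rejects unstable systems", {
  tr <- gen_var(matrix(0, 2, 2), sigma = diag(c(1, 4)), n_trials = 40,
                trial_length = 250, seed = 6)
  x <- matrix(aperm(tr, c(2, 1, 3)), nrow = 2)
  expect_equal(unname(tcrossprod(x) / ncol(x)), diag(c(1, 4)),
               tolerance = 0.15)
  expect_identical(tr, gen_var(matrix(0, 2, 2), sigma = diag(c(1, 4)),
                               n_trials = 40, trial_length = 250, seed = 6))
  expect_error(gen_var(matrix(c(1.2, 0, 0, 0.5), 2)), "unstable")
})

test_that("tuned spike generation hits its planted intensities", {
  units <- tibble::tibble(a = c(0, 8), b = c(2, 1), mu = c(5, 5),
                          w = c(1.5, 1.5))
  gt <- gen_tuned_spikes(units, n_timesteps = 60000, seed = 3)
  # homogeneous unit: empirical rate per window ~= b
  r1 <- length(gt$spikes[[1]]) / 60000 * 100
  expect_equal(r1, 2, tolerance = 3 * sqrt(2 / 600) / 2)
  # tuned unit at the preferred stimulus: rate ~= a + b
  at_mu <- gt$stimulus == 5
  r2 <- sum(gt$spikes[[2]] %in% which(at_mu)) / sum(at_mu) * 100
  se <- 100 * sqrt(9 / 100 / sum(at_mu))
  expect_equal(r2, 9, tolerance = 3 * se)
  expect_identical(gt$spikes,
                   gen_tuned_spikes(units, 60000, seed = 3)$spikes)
})

test_that("planted NMF and SBM surrogates match their parameters", {
  W <- matrix(1:6 / 6, 3, 2)
  H <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3)
  expect_equal(gen_planted_nmf(W, H, noise_sd = 0), W %*% H)
  X <- gen_planted_nmf(W, H, noise_sd = 0.1, seed = 4)
  expect_true(all(X >= 0))
  expect_identical(X, gen_planted_nmf(W, H, 0.1, seed = 4))

  g <- gen_planted_sbm(c(40, 40), p_in = 0.6, p_out = 0.05, seed = 5)
  same <- outer(g$labels, g$labels, "==")
  diag(same) <- NA
  dens_in <- mean(vapply(g$graphs, function(A) {
    mean(A[which(same)])
  }, double(1)))
  dens_out <- mean(vapply(g$graphs, function(A) {
    mean(A[which(!same)])
  }, double(1)))
  expect_lt(abs(dens_in - 0.6), 3 * sqrt(0.24 / (6 * 2 * 40 * 39)))
  expect_lt(abs(dens_out - 0.05), 3 * sqrt(0.0475 / (6 * 3200)))
})
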