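test_that("NAND gate reproduces its truth table", {
  nl <- nand_netlist()
  stim <- stimulus_program(nl, expand.grid(a = 0:1, b = 0:1))
  tr <- run_trace(nl, stim)
  out <- tr$wire_values[, as.character(wire_id(nl, "out"))]
  expect_equal(unname(out), c(1L, 1L, 1L, 0L)) # (0,0),(1,0),(0,1),(1,1)
})

test_that("an isolated charged group retains its value", {
  nl <- empty_netlist()
  nl <- add_wire(nl, "clk", role = "input")
  nl <- add_wire(nl, "d", role = "input")
  nl <- add_wire(nl, "s") # storage node, no pullup
  nl <- add_transistor(nl, "clk", "d", "s")
  stim <- stimulus_program(nl, cbind(clk = c(1L, 0L, 0L, 1L, 0L),
                                     d = c(1L, 0L, 0L, 0L, 0L)))
  tr <- run_trace(nl, stim)
  s <- tr$wire_values[, as.character(wire_id(nl, "s"))]
  # captured high at t1, held while clk low, overwritten low at t4
  expect_equal(unname(s), c(1L, 1L, 1L, 0L, 0L))
})

test_that("simulation is deterministic and matches the relaxation oracle", {
  for (s in 1:25) {
    nl <- random_netlist(seed = s)
    stim <- random_stimulus(nl, n_steps = 4, seed = s)
    got <- tryCatch(run_trace(nl, stim), error = function(e) "unstable")
    ref <- oracle_run(nl, stim)
    if (identical(got, "unstable")) {
      expect_false(ref$stable)
    } else {
      expect_true(ref$stable)
      expect_equal(unname(got$wire_values), ref$wire_values)
      expect_equal(unname(got$transistor_on), ref$transistor_on)
      again <- run_trace(nl, stim)
      expect_identical(got$wire_values, again$wire_values)
    }
  }
})

test_that("a self-inverting loop is reported unstable with the wires involved", {
  nl <- empty_netlist()
  nl <- add_wire(nl, "in", role = "input")
  nl <- add_wire(nl, "osc", pullup = TRUE)
  nl <- add_transistor(nl, "osc", "osc", silicophys:::ground_id(nl))
  stim <- stimulus_program(nl, matrix(0L, 2, 1,
                                      dimnames = list(NULL, "in")))
  expect_error(run_trace(nl, stim), "unstable")
  expect_error(run_trace(nl, stim),
               as.character(wire_id(nl, "osc")))
})

test_that("a two-phase shift register delays the pattern by its pipeline depth", {
  nl <- shift4_netlist()
  n_clocks <- 12L
  pat <- c(1L, 0L, 1L, 1L, rep(0L, n_clocks - 4))
  m <- cbind(clk0 = rep(c(1L, 0L), n_clocks),
             clk1 = rep(c(0L, 1L), n_clocks),
             sin = rep(pat, each = 2))
  tr <- run_trace(nl, stimulus_program(nl, m))
  q3 <- signal_trace(tr, "Q3")[seq(2, 2 * n_clocks, 2)]
  expect_equal(q3[4:7], pat[1:4]) # emerges after the 4-stage latency
  expect_equal(q3[1:3], rep(0L, 3))
})

test_that("stuck-on lesion of an inverter pulldown forces the output low", {
  nl <- inverter_netlist()
  stim <- stimulus_program(nl, matrix(c(0L, 1L, 0L, 1L), ncol = 1,
                                      dimnames = list(NULL, "in")))
  out_col <- as.character(wire_id(nl, "out"))
  expect_equal(unname(run_trace(nl, stim)$wire_values[, out_col]),
               c(1L, 0L, 1L, 0L))
  les <- run_trace(nl, stim, lesions = lesion(0L, "stuck_on"))
  expect_equal(unname(les$wire_values[, out_col]), rep(0L, 4))
  off <- run_trace(nl, stim, lesions = lesion(0L, "stuck_off"))
  expect_equal(unname(off$wire_values[, out_col]), rep(1L, 4))
})

test_that("lesion screen classifies by disrupted behaviors and partitions", {
  nl <- adder1_netlist()
  grid <- expand.grid(a = 0:1, b = 0:1, cin = 0:1)
  stim <- stimulus_program(nl, as.matrix(grid))
  expected_s <- (grid$a + grid$b + grid$cin) %% 2
  expected_c <- (grid$a + grid$b + grid$cin) %/% 2
  pred <- function(tr) {
    all(tr$wire_values[, as.character(wire_id(nl, "s"))] == expected_s) &&
      all(tr$wire_values[, as.character(wire_id(nl, "cout"))] == expected_c)
  }
  scr <- lesion_screen(nl, list(truth = list(stimulus = stim,
                                             predicate = pred)))
  expect_equal(nrow(scr), nrow(nl$transistors))
  counts <- table(factor(scr$class, levels = c("none", "some", "all")))
  expect_equal(sum(counts), nrow(nl$transistors))
  # dual route: per-transistor necessity from the independent oracle
  s_col <- match(wire_id(nl, "s"), nl$wires$id)
  c_col <- match(wire_id(nl, "cout"), nl$wires$id)
  necessary <- vapply(nl$transistors$id, function(tid) {
    res <- oracle_run(nl, stim, lesions = lesion(tid, "stuck_on"))
    !res$stable || !all(res$wire_values[, s_col] == expected_s) ||
      !all(res$wire_values[, c_col] == expected_c)
  }, logical(1))
  expect_equal(scr$truth, necessary)
})
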