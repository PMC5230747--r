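#' Ground-truth circuit fixtures
#'
#' Builds one of the shipped synthetic circuits together with its
#' ground-truth registry: module labels per transistor, named control
#' signals, behaviors (stimulus programs with expected output streams and a
#' success-prefix length for lesion screening), and the planted parameters
#' used by the surrogate-data generators. Every fixture verifies its own
#' expected outputs by simulation at build time and aborts on mismatch.
#'
#' Fixtures:
#' * `adder4` — combinational 4-bit ripple-carry adder (ground truth: 4-bit
#'   arithmetic over all 256 input pairs).
#' * `shiftreg8` — 8-stage two-phase-clocked shift register (ground truth:
#'   the input pattern reappears on the output 8 clocks later).
#' * `counter3_decoder` — 3-bit synchronous counter plus 3-to-8 decoder,
#'   with the three bit cells laid out in well-separated spatial clusters so
#'   region-specific periodicities (4, 8, 16 timesteps, i.e. 2, 4, 8 clock
#'   cycles) are recoverable from field-potential channels.
#' * `microfsm` — two-phase-clocked micro machine (~200 transistors) with
#'   annotated submodules (control, program counter, decoder, adder,
#'   accumulator, output register), a read/write-analogue control line that
#'   alternates fetch and write phases, and >= 3 operand "behaviors" that
#'   emit distinct scalar output streams.
#'
#' @param name fixture name.
#' @param seed integer seed (fixtures are deterministic; the seed is
#'   recorded in the registry and used by downstream surrogate draws).
#' @return a `fixture`: list with `netlist` and `registry`.
#' @export
make_fixture <- function(name = c("adder4", "shiftreg8", "counter3_decoder",
                                  "microfsm"), seed = 1) {
  name <- match.arg(name)
  fix <- switch(name,
                adder4 = fixture_adder4(),
                shiftreg8 = fixture_shiftreg8(),
                counter3_decoder = fixture_counter3(),
                microfsm = fixture_microfsm())
  fix$registry$seed <- seed
  fix$registry$planted <- planted_defaults()
  class(fix) <- "fixture"
  check_fixture(fix)
  fix
}

#' @export
print.fixture <- function(x, ...) {
  cat("<fixture '", x$registry$fixture, "'> ", sep = "")
  print(x$netlist)
  cat("  behaviors: ", paste(names(x$registry$behaviors), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# planted surrogate parameters shared by every fixture's registry: these are
# the study conditions the validation battery is scored under
planted_defaults <- function() {
  A1 <- matrix(c(0.5, 0.0, 0.1, 0.4), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.2, 0.0, 0.0, -0.15), 2, 2, byrow = TRUE)
  A3 <- matrix(c(0.0, 0.3, 0.35, 0.0), 2, 2, byrow = TRUE)
  list(
    tuning = list(a = 8, b = 1, mu = 5, w = 1.5,
                  stim_values = 0:10, block_len = 250, window = 100),
    var3 = list(coef = array(c(A1, A2, A3), c(2, 2, 3)), order = 3),
    gc_chain = list(xy = 0.9, yz = 0.8),
    nmf = list(k = 4, n_units = 60, n_bins = 400, noise_sd = 0.02),
    sbm = list(block_sizes = c(30, 30, 30), p_in = 0.6, p_out = 0.05))
}

# run every behavior of a fixture and compare sampled outputs with the
# registry's expected streams; abort on mismatch (fixture bug)
check_fixture <- function(fix) {
  for (bname in names(fix$registry$behaviors)) {
    bh <- fix$registry$behaviors[[bname]]
    tr <- run_trace(fix$netlist, bh$stimulus)
    got <- bh$read_output(tr)
    if (!identical(as.integer(got), as.integer(bh$expected_output))) {
      stop("fixture self-check failed for '", fix$registry$fixture,
           "' behavior '", bname, "'")
    }
  }
  invisible(fix)
}

#' Success predicate for a registry behavior
#'
#' Builds the lesion-screen predicate: the behavior succeeds when the first
#' `success_prefix` samples of its output stream match the registry's
#' expected stream (the analogue of drawing the first output frame).
#'
#' @param behavior one element of `registry$behaviors`.
#' @return function(trace) -> logical.
#' @export
behavior_predicate <- function(behavior) {
  k <- behavior$success_prefix
  expected <- as.integer(behavior$expected_output[seq_len(k)])
  function(trace) {
    got <- as.integer(behavior$read_output(trace)[seq_len(k)])
    identical(got, expected)
  }
}

# ---- adder4 ---------------------------------------------------------------

# one ripple-carry full adder: s = a xor b xor cin,
# cout = nand(nand(a,b), nand(a xor b, cin))
add_full_adder <- function(nl, a, b, cin, s, cout, at, module) {
  pre <- if (nrow(nl$transistors)) max(nl$transistors$id) + 1L else 0L
  g1 <- paste0(s, ".g1")
  nl <- add_wire(nl, g1)
  n1 <- paste0(s, ".n1"); n2 <- paste0(s, ".n2")
  nl <- add_wire(nl, n1)
  nl <- add_wire(nl, n2)
  nl <- add_gate(nl, "xor2", c(a, b), g1, at)
  nl <- add_gate(nl, "xor2", c(g1, cin), s, at + c(20, 0))
  nl <- add_gate(nl, "nand2", c(a, b), n1, at + c(0, 20))
  nl <- add_gate(nl, "nand2", c(g1, cin), n2, at + c(10, 20))
  nl <- add_gate(nl, "nand2", c(n1, n2), cout, at + c(20, 20))
  add_module(nl, module, seq.int(pre, max(nl$transistors$id)))
}

fixture_adder4 <- function() {
  nl <- empty_netlist()
  abits <- paste0("a", 0:3)
  bbits <- paste0("b", 0:3)
  sbits <- paste0("s", 0:3)
  for (w in c(abits, bbits, "cin")) nl <- add_wire(nl, w, role = "input")
  for (w in c(sbits, "cout")) nl <- add_wire(nl, w, role = "output")
  carries <- c("cin", paste0("c", 1:3), "cout")
  for (w in paste0("c", 1:3)) nl <- add_wire(nl, w)
  for (i in 0:3) {
    nl <- add_full_adder(nl, abits[i + 1], bbits[i + 1], carries[i + 1],
                         sbits[i + 1], carries[i + 2],
                         at = c(200 * i, 0), module = paste0("fa", i))
  }
  for (s in c(abits, bbits, sbits, "cin", "cout")) {
    nl <- add_signal(nl, toupper(s), s)
  }

  grid <- expand.grid(a = 0:15, b = 0:15)
  bits <- function(v, n) vapply(0:(n - 1), function(k) (v %/% 2^k) %% 2,
                                numeric(length(v)))
  stim_m <- cbind(bits(grid$a, 4), bits(grid$b, 4), 0L)
  colnames(stim_m) <- c(abits, bbits, "cin")
  stim <- stimulus_program(nl, stim_m)
  expected <- as.integer(grid$a + grid$b)
  behaviors <- list(exhaustive = list(
    stimulus = stim,
    expected_output = expected,
    read_output = function(tr) bus_trace(tr, toupper(c(sbits, "cout"))),
    success_prefix = length(expected)))
  list(netlist = nl,
       registry = list(fixture = "adder4", behaviors = behaviors,
                       signals = names(nl$signals)))
}

# ---- shiftreg8 ------------------------------------------------------------

fixture_shiftreg8 <- function() {
  nl <- empty_netlist()
  for (w in c("clk0", "clk1", "sin")) nl <- add_wire(nl, w, role = "input")
  qs <- paste0("q", 0:7)
  for (i in 0:6) nl <- add_wire(nl, qs[i + 1])
  nl <- add_wire(nl, "q7", role = "output")
  din <- c("sin", qs[1:7])
  for (i in 0:7) {
    pre <- if (nrow(nl$transistors)) max(nl$transistors$id) + 1L else 0L
    nl <- add_gate(nl, "dff_2phase", c(din[i + 1], "clk0", "clk1"), qs[i + 1],
                   at = c(300 * i, 0))
    nl <- add_module(nl, paste0("stage", i),
                     seq.int(pre, max(nl$transistors$id)))
  }
  nl <- add_signal(nl, "CLK0", "clk0")
  nl <- add_signal(nl, "CLK1", "clk1")
  for (q in qs) nl <- add_signal(nl, toupper(q), q)

  pattern <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  n_clocks <- 24L
  sin_per_clock <- c(pattern, rep(0L, n_clocks - length(pattern)))
  m <- cbind(rep(c(1L, 0L), n_clocks), rep(c(0L, 1L), n_clocks),
             rep(sin_per_clock, each = 2))
  colnames(m) <- c("clk0", "clk1", "sin")
  stim <- stimulus_program(nl, m)
  # stage 0 registers its input within the presenting clock, and each later
  # stage adds one clock: q7 at the end of clock c carries the bit presented
  # during clock c - 7
  expected <- vapply(seq_len(n_clocks), function(c) {
    if (c > 7) sin_per_clock[c - 7] else 0L
  }, integer(1))
  behaviors <- list(shift = list(
    stimulus = stim,
    expected_output = expected,
    read_output = function(tr) {
      signal_trace(tr, "Q7")[seq(2, by = 2, length.out = n_clocks)]
    },
    success_prefix = n_clocks))
  list(netlist = nl,
       registry = list(fixture = "shiftreg8", behaviors = behaviors,
                       signals = names(nl$signals)))
}

# ---- counter3_decoder -----------------------------------------------------

# 3-bit synchronous counter: d0 = !q0, d1 = q1 xor q0, d2 = q2 xor (q0 & q1)
add_counter3 <- function(nl, qs, clk0, clk1, ats, modules) {
  nq0 <- paste0(qs[1], ".n")
  nl <- add_wire(nl, nq0)
  pre <- max(c(-1L, nl$transistors$id)) + 1L
  nl <- add_gate(nl, "not", qs[1], nq0, ats[[1]])
  nl <- add_gate(nl, "dff_2phase", c(nq0, clk0, clk1), qs[1],
                 ats[[1]] + c(12, 0))
  nl <- add_module(nl, modules[1], seq.int(pre, max(nl$transistors$id)))

  d1 <- paste0(qs[2], ".d")
  nl <- add_wire(nl, d1)
  pre <- max(nl$transistors$id) + 1L
  nl <- add_gate(nl, "xor2", c(qs[2], qs[1]), d1, ats[[2]])
  nl <- add_gate(nl, "dff_2phase", c(d1, clk0, clk1), qs[2],
                 ats[[2]] + c(20, 0))
  nl <- add_module(nl, modules[2], seq.int(pre, max(nl$transistors$id)))

  t12 <- paste0(qs[3], ".t")
  d2 <- paste0(qs[3], ".d")
  nl <- add_wire(nl, t12)
  nl <- add_wire(nl, d2)
  pre <- max(nl$transistors$id) + 1L
  nl <- add_gate(nl, "and2", c(qs[1], qs[2]), t12, ats[[3]])
  nl <- add_gate(nl, "xor2", c(qs[3], t12), d2, ats[[3]] + c(12, 0))
  nl <- add_gate(nl, "dff_2phase", c(d2, clk0, clk1), qs[3],
                 ats[[3]] + c(32, 0))
  nl <- add_module(nl, modules[3], seq.int(pre, max(nl$transistors$id)))
  nl
}

fixture_counter3 <- function() {
  nl <- empty_netlist()
  for (w in c("clk0", "clk1")) nl <- add_wire(nl, w, role = "input")
  qs <- paste0("q", 0:2)
  for (q in qs) nl <- add_wire(nl, q, role = "output")
  nl <- add_counter3(nl, qs, "clk0", "clk1",
                     ats = list(c(0, 0), c(4000, 0), c(8000, 0)),
                     modules = paste0("bit", 0:2))
  # 3-to-8 decoder in its own spatial cluster
  nq1 <- "q1.dn"; nq2 <- "q2.dn"
  nl <- add_wire(nl, nq1)
  nl <- add_wire(nl, nq2)
  pre <- max(nl$transistors$id) + 1L
  nl <- add_gate(nl, "not", "q1", nq1, c(12000, 0))
  nl <- add_gate(nl, "not", "q2", nq2, c(12000, 8))
  lits <- list(c("q0.n", nq1, nq2), c("q0", nq1, nq2),
               c("q0.n", "q1", nq2), c("q0", "q1", nq2),
               c("q0.n", nq1, "q2"), c("q0", nq1, "q2"),
               c("q0.n", "q1", "q2"), c("q0", "q1", "q2"))
  for (s in 0:7) {
    dw <- paste0("dec", s)
    nl <- add_wire(nl, dw)
    nl <- add_gate(nl, "and3", lits[[s + 1]], dw, c(12000 + 40 * (s %% 4),
                                                    30 + 40 * (s %/% 4)))
  }
  nl <- add_module(nl, "decoder", seq.int(pre, max(nl$transistors$id)))
  nl <- add_signal(nl, "CLK0", "clk0")
  nl <- add_signal(nl, "CLK1", "clk1")
  for (k in 0:2) nl <- add_signal(nl, paste0("BIT", k), qs[k + 1])
  for (s in 0:7) nl <- add_signal(nl, paste0("DEC", s), paste0("dec", s))

  n_clocks <- 64L
  stim <- two_phase_stimulus(nl, n_clocks)
  expected <- seq_len(n_clocks) %% 8L
  behaviors <- list(count = list(
    stimulus = stim,
    expected_output = expected,
    read_output = function(tr) {
      bus_trace(tr, paste0("BIT", 0:2))[seq(2, by = 2, length.out = n_clocks)]
    },
    success_prefix = 16L))
  list(netlist = nl,
       registry = list(
         fixture = "counter3_decoder", behaviors = behaviors,
         signals = names(nl$signals),
         bit_periods = c(bit0 = 4L, bit1 = 8L, bit2 = 16L)))
}

# ---- microfsm -------------------------------------------------------------

fixture_microfsm <- function() {
  nl <- empty_netlist()
  for (w in c("clk0", "clk1", paste0("op", 0:3))) {
    nl <- add_wire(nl, w, role = "input")
  }
  # constant-low helper wire: never driven, no pullup, stays low
  nl <- add_wire(nl, "lo")

  # control: RW flip-flop toggling every clock (master samples on clk0,
  # slave transfers on clk1, so RW is stable through every clk0 half)
  nl <- add_wire(nl, "rw")
  nl <- add_wire(nl, "rwb")
  pre <- 0L
  nl <- add_gate(nl, "dff_2phase", c("rwb", "clk0", "clk1"), "rw", c(0, 0))
  nl <- add_gate(nl, "not", "rw", "rwb", c(30, 0))
  nl <- add_module(nl, "control", seq.int(pre, max(nl$transistors$id)))

  # clock tree and control-line distribution: inverter chains that buffer
  # the two clock phases and the read/write line across the die, as a real
  # processor's clock/control distribution does; their transistors follow
  # the distributed line wholesale, which is what makes the population
  # activity clock- and RW-dominated
  pre <- max(nl$transistors$id) + 1L
  for (ph in c("clk0", "clk1")) {
    for (k in 1:8) {
      w <- sprintf("%s.t%d", ph, k)
      nl <- add_wire(nl, w)
      nl <- add_gate(nl, "not", ph, w,
                     c(500 + 20 * k, if (ph == "clk0") 0 else 40))
    }
  }
  nl <- add_module(nl, "clktree", seq.int(pre, max(nl$transistors$id)))
  pre <- max(nl$transistors$id) + 1L
  for (k in 1:8) {
    w <- sprintf("rw.t%d", k)
    nl <- add_wire(nl, w)
    nl <- add_gate(nl, "not", "rw", w, c(500 + 20 * k, 80))
  }
  nl <- add_module(nl, "rwdist", seq.int(pre, max(nl$transistors$id)))

  # program counter: 3-bit synchronous counter
  pcs <- paste0("pc", 0:2)
  for (p in pcs) nl <- add_wire(nl, p)
  nl <- add_counter3(nl, pcs, "clk0", "clk1",
                     ats = list(c(2000, 0), c(2000, 40), c(2000, 80)),
                     modules = c("pc", "pc", "pc"))

  # decoder: 3-to-8 over the program counter
  npc1 <- "pc1.dn"; npc2 <- "pc2.dn"
  nl <- add_wire(nl, npc1)
  nl <- add_wire(nl, npc2)
  pre <- max(nl$transistors$id) + 1L
  nl <- add_gate(nl, "not", "pc1", npc1, c(4000, 0))
  nl <- add_gate(nl, "not", "pc2", npc2, c(4000, 8))
  lits <- list(c("pc0.n", npc1, npc2), c("pc0", npc1, npc2),
               c("pc0.n", "pc1", npc2), c("pc0", "pc1", npc2),
               c("pc0.n", npc1, "pc2"), c("pc0", npc1, "pc2"),
               c("pc0.n", "pc1", "pc2"), c("pc0", "pc1", "pc2"))
  for (s in 0:7) {
    dw <- paste0("dec", s)
    nl <- add_wire(nl, dw)
    nl <- add_gate(nl, "and3", lits[[s + 1]], dw,
                   c(4000 + 40 * (s %% 4), 30 + 40 * (s %/% 4)))
  }
  nl <- add_module(nl, "decoder", seq.int(pre, max(nl$transistors$id)))

  # instruction modifier: operand bit 0 flips in program-counter state 7
  nl <- add_wire(nl, "eff0")
  pre <- max(nl$transistors$id) + 1L
  nl <- add_gate(nl, "xor2", c("op0", "dec7"), "eff0", c(4000, 120))
  nl <- add_module(nl, "decoder", seq.int(pre, max(nl$transistors$id)))

  # 4-bit adder: accumulator + effective operand
  accs <- paste0("acc", 0:3)
  sums <- paste0("sum", 0:3)
  for (w in c(accs, sums, paste0("ac", 1:3), "acout")) nl <- add_wire(nl, w)
  bsrc <- c("eff0", paste0("op", 1:3))
  car <- c("lo", paste0("ac", 1:3), "acout")
  for (i in 0:3) {
    nl <- add_full_adder(nl, accs[i + 1], bsrc[i + 1], car[i + 1],
                         sums[i + 1], car[i + 2],
                         at = c(6000 + 200 * i, 0), module = "adder")
  }

  # accumulator: register clocked on both phases; its data input is fed
  # from the adder sum through a single pass transistor gated by RW. On
  # fetch clocks (rw high) the mux node tracks the sum; on write clocks it
  # floats and charge retention holds the last captured sum, which equals
  # the current accumulator value, so the register recirculates
  pre <- max(nl$transistors$id) + 1L
  for (i in 0:3) {
    dmux <- paste0("accd", i)
    nl <- add_wire(nl, dmux)
    p <- c(8000 + 60 * i, 0)
    nl <- add_transistor(nl, "rw", sums[i + 1], dmux, p[1], p[2])
    nl <- add_gate(nl, "dff_2phase", c(dmux, "clk0", "clk1"),
                   accs[i + 1], at = p + c(8, 0))
  }
  nl <- add_module(nl, "acc", seq.int(pre, max(nl$transistors$id)))

  # output register: pipeline latch refreshed from the accumulator on
  # every clk1 phase
  outs <- paste0("out", 0:3)
  for (i in 0:2) nl <- add_wire(nl, outs[i + 1])
  nl <- add_wire(nl, "out3", role = "output")
  pre <- max(nl$transistors$id) + 1L
  for (i in 0:3) {
    nl <- add_gate(nl, "pass_latch", c(accs[i + 1], "clk1"), outs[i + 1],
                   at = c(10000 + 40 * i, 0))
  }
  nl <- add_module(nl, "outreg", seq.int(pre, max(nl$transistors$id)))

  nl <- add_signal(nl, "CLK0", "clk0")
  nl <- add_signal(nl, "CLK1", "clk1")
  nl <- add_signal(nl, "RW", "rw")
  nl <- add_signal(nl, "RWB", "rwb")
  for (k in 0:2) nl <- add_signal(nl, paste0("PC", k), pcs[k + 1])
  for (s in 0:7) nl <- add_signal(nl, paste0("DEC", s), paste0("dec", s))
  for (k in 0:3) nl <- add_signal(nl, paste0("ACC", k), accs[k + 1])
  for (k in 0:3) nl <- add_signal(nl, paste0("SUM", k), sums[k + 1])
  for (k in 0:3) nl <- add_signal(nl, paste0("OUT", k), outs[k + 1])
  nl <- add_signal(nl, "EFF0", "eff0")

  behaviors <- list()
  for (op in c(1L, 3L, 5L)) {
    behaviors[[paste0("op", op)]] <- microfsm_behavior(nl, op, n_clocks = 64L)
  }
  list(netlist = nl,
       registry = list(fixture = "microfsm", behaviors = behaviors,
                       signals = names(nl$signals)))
}

# abstract model of the microfsm, used both for expected outputs and as an
# independent check of the transistor-level implementation:
# clock c: pc = (c-1) mod 8; rw = (c even) during the fetch half; on fetch
# clocks the accumulator adds the effective operand (bit 0 xored with
# [pc == 7]); the output register copies the accumulator every clock
microfsm_model <- function(op, n_clocks) {
  acc <- 0L
  out_seq <- integer(n_clocks)
  acc_seq <- integer(n_clocks)
  for (c in seq_len(n_clocks)) {
    pc <- (c - 1L) %% 8L
    rw <- as.integer(c %% 2L == 0L)
    if (rw == 1L) {
      eff <- bitwXor(op, as.integer(pc == 7L) * 1L)
      acc <- (acc + eff) %% 16L
    }
    out_seq[c] <- acc
    acc_seq[c] <- acc
  }
  list(out = out_seq, acc = acc_seq)
}

microfsm_behavior <- function(nl, op, n_clocks) {
  consts <- as.list(stats::setNames(
    vapply(0:3, function(k) as.integer((op %/% 2^k) %% 2), integer(1)),
    paste0("op", 0:3)))
  stim <- two_phase_stimulus(nl, n_clocks, constants = consts)
  model <- microfsm_model(op, n_clocks)
  list(stimulus = stim,
       expected_output = model$out,
       read_output = function(tr) {
         bus_trace(tr, paste0("OUT", 0:3))[seq(2, by = 2,
                                               length.out = n_clocks)]
       },
       success_prefix = 16L,
       operand = op)
}

# ---- surrogate generators -------------------------------------------------

#' Simulate a vector autoregression as a trial set
#'
#' Draws independent trials from a VAR(p) with Gaussian innovations. The
#' process must be stationary: the companion-matrix spectral radius has to
#' be below 1 or an error is raised. Each trial gets its own burn-in, so
#' trials are exchangeable.
#'
#' @param coef p x m x m array (or m x m matrix for p = 1):
#'   `coef[l, i, j]` is the effect of channel j at lag l on channel i.
#' @param sigma m x m innovation covariance (default identity).
#' @param n_trials,trial_length trial grid (paper-style default: 100
#'   trials).
#' @param seed integer seed; same seed, same array.
#' @param burn_in samples discarded at the start of each trial.
#' @return a `trial_set` array (trial, channel, time) with channels named
#'   `ch1..chm`.
#' @export
gen_var <- function(coef, sigma = NULL, n_trials = 100, trial_length = 1000,
                    seed = 1, burn_in = 100) {
  if (is.matrix(coef)) coef <- array(coef, c(1, nrow(coef), ncol(coef)))
  if (length(dim(coef)) == 3 && dim(coef)[2] != dim(coef)[3]) {
    stop("coef must be p x m x m")
  }
  p <- dim(coef)[1]
  m <- dim(coef)[2]
  if (is.null(sigma)) sigma <- diag(m)
  # companion form stability check
  comp <- matrix(0, m * p, m * p)
  for (l in seq_len(p)) comp[1:m, ((l - 1) * m + 1):(l * m)] <- coef[l, , ]
  if (p > 1) comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) stop("unstable VAR: companion spectral radius ", round(rho, 3),
                     " >= 1")
  ch <- chol(sigma)
  withr_seed(seed, {
    out <- array(NA_real_, c(n_trials, m, trial_length),
                 dimnames = list(NULL, paste0("ch", 1:m), NULL))
    total <- burn_in + trial_length
    for (r in seq_len(n_trials)) {
      eps <- matrix(stats::rnorm(total * m), m, total)
      eps <- t(ch) %*% eps
      x <- matrix(0, m, total)
      for (t in seq_len(total)) {
        v <- eps[, t]
        for (l in seq_len(p)) {
          if (t - l >= 1) v <- v + coef[l, , ] %*% x[, t - l]
        }
        x[, t] <- v
      }
      out[r, , ] <- x[, (burn_in + 1):total]
    }
    out
  })
}

#' Poisson-like spike trains with planted Gaussian tuning
#'
#' The stimulus is a block sequence: each block holds one value drawn
#' uniformly from `stim_values` for `block_len` timesteps (persistence is
#' what lets a trailing-window rate estimator see the tuning). Each unit
#' spikes independently per timestep with probability
#' `lambda(s) / window`, where
#' `lambda(s) = a exp(-(s - mu)^2 / (2 w^2)) + b` is the expected count per
#' rate window.
#'
#' @param units tibble/data frame with columns `a`, `b`, `mu`, `w`, one row
#'   per unit.
#' @param n_timesteps total length.
#' @param seed integer seed.
#' @param stim_values discrete stimulus values (default 0:10).
#' @param block_len stimulus persistence in timesteps (default 250).
#' @param window the rate window the intensities refer to (default 100).
#' @return list with `spikes` (a `spike_set`), `stimulus` (integer vector),
#'   and `lambda` (units x values matrix of planted expected rates).
#' @export
gen_tuned_spikes <- function(units, n_timesteps, seed = 1,
                             stim_values = 0:10, block_len = 250,
                             window = 100) {
  units <- tibble::as_tibble(units)
  withr_seed(seed, {
    n_blocks <- ceiling(n_timesteps / block_len)
    stim <- rep(sample(stim_values, n_blocks, replace = TRUE),
                each = block_len)[seq_len(n_timesteps)]
    lam <- t(apply(units, 1, function(u) {
      u["a"] * exp(-(stim_values - u["mu"])^2 / (2 * u["w"]^2)) + u["b"]
    }))
    colnames(lam) <- stim_values
    pr <- lam[, match(stim, stim_values), drop = FALSE] / window
    if (any(pr > 1)) stop("per-timestep spike probability exceeds 1")
    spikes <- lapply(seq_len(nrow(units)), function(i) {
      which(stats::runif(n_timesteps) < pr[i, ])
    })
    names(spikes) <- as.character(seq_len(nrow(units)))
    list(spikes = structure(spikes, class = "spike_set",
                            n_timesteps = n_timesteps),
         stimulus = stim, lambda = lam)
  })
}

#' Planted non-negative factorization data
#'
#' @param W,H non-negative factor matrices.
#' @param noise_sd Gaussian noise standard deviation; the result is
#'   clipped at zero to stay non-negative.
#' @param seed integer seed.
#' @return matrix `pmax(W H + noise, 0)`.
#' @export
gen_planted_nmf <- function(W, H, noise_sd = 0, seed = 1) {
  stopifnot(all(W >= 0), all(H >= 0), ncol(W) == nrow(H))
  X <- W %*% H
  if (noise_sd > 0) {
    X <- withr_seed(seed, X + matrix(stats::rnorm(length(X), 0, noise_sd),
                                     nrow(X)))
  }
  pmax(X, 0)
}

#' Planted multi-relation stochastic block model graphs
#'
#' Draws six directed Bernoulli adjacency matrices sharing one planted
#' partition: within-block edges with probability `p_in`, between-block
#' with `p_out`, no self-edges.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out edge probabilities.
#' @param seed integer seed.
#' @param n_relations number of relations (default 6).
#' @return list with `graphs` (named list of 0/1 matrices) and `labels`
#'   (planted block of each node).
#' @export
gen_planted_sbm <- function(block_sizes, p_in = 0.6, p_out = 0.05, seed = 1,
                            n_relations = 6) {
  z <- rep(seq_along(block_sizes), block_sizes)
  n <- length(z)
  P <- matrix(p_out, n, n)
  same <- outer(z, z, "==")
  P[same] <- p_in
  diag(P) <- 0
  withr_seed(seed, {
    graphs <- lapply(seq_len(n_relations), function(r) {
      (matrix(stats::runif(n * n), n, n) < P) * 1L
    })
    names(graphs) <- c("G_C1", "G_C2", "C1_C2", "C2_C1", "C1_G",
                       "C2_G")[seq_len(n_relations)]
    list(graphs = graphs, labels = z)
  })
}
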