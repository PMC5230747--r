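#' Settle a circuit to its fixed point
#'
#' Runs synchronous relaxation passes until no wire changes value. In each
#' pass, a transistor conducts iff its gate wire is high (lesions override
#' this), wires connected through conducting channels form a group, and the
#' group value follows the precedence: ground member -> low; else power
#' member -> high; else any pullup -> high; else any member high at the
#' start of the pass -> high (charge retention); else low. Power and ground
#' keep their rail values regardless of grouping.
#'
#' @param nl a `netlist`.
#' @param wire_values optional named (by wire id) or unnamed integer/logical
#'   vector of initial wire values, ordered like `nl$wires`; defaults to all
#'   low except power.
#' @param lesions optional tibble from [lesion()].
#' @param max_passes settling pass cap; default `100 * n_wires`. Exceeding
#'   it raises an "unstable" error reporting the oscillating wires.
#' @return list with `wire_values` and `transistor_on` (named 0/1 vectors)
#'   and `passes`.
#' @export
resolve_state <- function(nl, wire_values = NULL, lesions = NULL,
                          max_passes = NULL) {
  a <- netlist_arrays(nl)
  if (is.null(max_passes)) max_passes <- 100L * nrow(nl$wires)
  init <- rep(0L, nrow(nl$wires))
  if (!is.null(wire_values)) {
    stopifnot(length(wire_values) == nrow(nl$wires))
    init <- as.integer(wire_values)
  }
  init[a$power + 1L] <- 1L
  init[a$ground + 1L] <- 0L
  pinned <- rep(-1L, nrow(nl$wires))
  is_input <- nl$wires$role == "input"
  pinned[is_input] <- init[is_input]
  res <- settle_cpp(a$gate, a$c1, a$c2, a$pullup, a$power, a$ground,
                    init, lesion_codes(nl, lesions), pinned, max_passes)
  if (!res$stable) {
    stop("unstable circuit: wires oscillating after ", max_passes,
         " passes: ", paste(nl$wires$id[res$oscillating + 1L], collapse = ", "))
  }
  list(wire_values = stats::setNames(res$wire, nl$wires$id),
       transistor_on = stats::setNames(res$ton, nl$transistors$id),
       passes = res$passes)
}

# 0-based terminal arrays for the C++ core, in tibble row order
netlist_arrays <- function(nl) {
  widx <- function(ids) match(ids, nl$wires$id) - 1L
  list(gate = widx(nl$transistors$gate),
       c1 = widx(nl$transistors$c1),
       c2 = widx(nl$transistors$c2),
       pullup = nl$wires$pullup,
       power = widx(power_id(nl)),
       ground = widx(ground_id(nl)))
}

lesion_codes <- function(nl, lesions) {
  codes <- rep(0L, nrow(nl$transistors))
  if (!is.null(lesions) && nrow(lesions)) {
    idx <- match(lesions$transistor, nl$transistors$id)
    if (anyNA(idx)) {
      stop("lesion references missing transistor id(s): ",
           paste(lesions$transistor[is.na(idx)], collapse = ", "))
    }
    codes[idx] <- ifelse(lesions$mode == "stuck_on", 1L, 2L)
  }
  codes
}

#' Describe transistor lesions
#'
#' `stuck_on` forces a transistor's channel to conduct permanently (the
#' input-forced-high intervention); `stuck_off` forbids conduction and is
#' provided as an extension, excluded from replication defaults.
#'
#' @param transistor integer transistor id(s).
#' @param mode `"stuck_on"` or `"stuck_off"`, recycled.
#' @return tibble with columns `transistor`, `mode`.
#' @export
lesion <- function(transistor, mode = "stuck_on") {
  stopifnot(all(mode %in% c("stuck_on", "stuck_off")))
  tibble::tibble(transistor = as.integer(transistor), mode = mode)
}

#' Build a stimulus program
#'
#' A stimulus program assigns every input wire a binary value at every
#' timestep. One timestep means: apply the assignment, then settle to a
#' fixed point; the recorded state is the post-settling one.
#'
#' @param nl a `netlist`.
#' @param values matrix or data frame, timesteps x inputs, with column names
#'   naming input wires; entries coerced to 0/1.
#' @return integer matrix of class `stimulus_program`.
#' @export
stimulus_program <- function(nl, values) {
  m <- as.matrix(values)
  storage.mode(m) <- "integer"
  inputs <- nl$wires$name[nl$wires$role == "input"]
  if (is.null(colnames(m)) || !setequal(colnames(m), inputs)) {
    stop("stimulus must assign exactly the input wires: ",
         paste(inputs, collapse = ", "))
  }
  if (length(inputs)) m <- m[, inputs, drop = FALSE]
  if (!all(m %in% c(0L, 1L))) stop("stimulus values must be 0/1")
  structure(m, class = c("stimulus_program", class(m)))
}

#' Two-phase clock stimulus
#'
#' Each clock cycle spans two timesteps: `clk0` high on the first, `clk1`
#' high on the second (non-overlapping phases). Additional inputs are held
#' at constant values.
#'
#' @param nl a `netlist`.
#' @param n_clocks number of clock cycles.
#' @param clk0,clk1 input wire names carrying the two phases.
#' @param constants named list/vector of constant 0/1 values for the
#'   remaining input wires.
#' @return a `stimulus_program` with `2 * n_clocks` timesteps.
#' @export
two_phase_stimulus <- function(nl, n_clocks, clk0 = "clk0", clk1 = "clk1",
                               constants = list()) {
  t_total <- 2L * n_clocks
  phase0 <- rep(c(1L, 0L), n_clocks)
  m <- cbind(phase0, 1L - phase0)
  colnames(m) <- c(clk0, clk1)
  for (nm in names(constants)) {
    m <- cbind(m, rep(as.integer(constants[[nm]]), t_total))
    colnames(m)[ncol(m)] <- nm
  }
  stimulus_program(nl, m)
}

#' Simulate a netlist under a stimulus program
#'
#' Deterministic: identical (netlist, stimulus, lesions) inputs give
#' bit-identical traces. The initial state is all wires low except power;
#' fixtures prepend whatever reset prefix they need to their programs.
#'
#' @param nl a `netlist`.
#' @param stimulus a `stimulus_program`.
#' @param lesions optional tibble from [lesion()].
#' @param max_passes settling cap per timestep (default `100 * n_wires`).
#' @return a `state_trace`: list with `wire_values` (T x n_wires 0/1
#'   matrix, columns named by wire id), `transistor_on` (T x n_transistors),
#'   and the originating `netlist`.
#' @export
run_trace <- function(nl, stimulus, lesions = NULL, max_passes = NULL) {
  stopifnot(inherits(stimulus, "stimulus_program"))
  a <- netlist_arrays(nl)
  if (is.null(max_passes)) max_passes <- 100L * nrow(nl$wires)
  input_ids <- wire_id(nl, colnames(stimulus))
  res <- run_cpp(a$gate, a$c1, a$c2, a$pullup, a$power, a$ground,
                 match(input_ids, nl$wires$id) - 1L,
                 unclass(stimulus), lesion_codes(nl, lesions), max_passes)
  if (!res$stable) {
    stop("unstable circuit at timestep ", res$timestep,
         ": oscillating wires ",
         paste(nl$wires$id[res$oscillating + 1L], collapse = ", "))
  }
  wv <- res$wire_values
  colnames(wv) <- nl$wires$id
  tv <- res$transistor_on
  colnames(tv) <- nl$transistors$id
  structure(list(wire_values = wv, transistor_on = tv, netlist = nl),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat("<state_trace> ", nrow(x$wire_values), " timesteps, ",
      ncol(x$wire_values), " wires, ", ncol(x$transistor_on),
      " transistors\n", sep = "")
  invisible(x)
}

#' Extract a signal's value sequence from a trace
#' @param trace a `state_trace`.
#' @param signal a signal name registered in the netlist, or a wire id.
#' @return integer 0/1 vector of length T.
#' @export
signal_trace <- function(trace, signal) {
  nl <- trace$netlist
  id <- if (is.character(signal)) {
    if (is.null(nl$signals[[signal]])) stop("unknown signal: ", signal)
    nl$signals[[signal]]
  } else as.integer(signal)
  as.integer(trace$wire_values[, as.character(id)])
}

#' Read a multi-bit bus value from a trace
#' @param trace a `state_trace`.
#' @param signals signal names, least-significant bit first.
#' @return integer vector of bus values per timestep.
#' @export
bus_trace <- function(trace, signals) {
  bits <- vapply(signals, function(s) signal_trace(trace, s),
                 integer(nrow(trace$wire_values)))
  as.integer(bits %*% 2^(seq_along(signals) - 1))
}

#' In-silico lesion screen
#'
#' Lesions every transistor in turn, reruns each behavior, and classifies
#' transistors by which behaviors they disrupt. A behavior is a stimulus
#' program plus a success predicate on the resulting trace (the analogue of
#' "does the system still draw its first output frame"). An unstable
#' lesioned circuit counts as a behavioral failure.
#'
#' @param nl a `netlist`.
#' @param behaviors named list; each element is `list(stimulus =, predicate
#'   = function(trace) TRUE/FALSE)`.
#' @param mode lesion mode applied to each transistor (default the
#'   replication mode `"stuck_on"`).
#' @param transistors ids to screen (default all).
#' @return tibble with one row per transistor: logical column per behavior
#'   (`TRUE` = behavior disrupted), `n_disrupted`, and `class` in
#'   `{"none","some","all"}`. Classification counts partition the
#'   transistor set.
#' @export
lesion_screen <- function(nl, behaviors, mode = "stuck_on",
                          transistors = nl$transistors$id) {
  stopifnot(length(behaviors) >= 1, !is.null(names(behaviors)))
  for (b in names(behaviors)) {
    base <- run_trace(nl, behaviors[[b]]$stimulus)
    if (!isTRUE(behaviors[[b]]$predicate(base))) {
      warning("behavior '", b, "' fails on the un-lesioned circuit")
    }
  }
  rows <- purrr::map_dfr(transistors, function(tid) {
    les <- lesion(tid, mode)
    hit <- vapply(behaviors, function(bh) {
      tr <- tryCatch(run_trace(nl, bh$stimulus, lesions = les),
                     error = function(e) NULL)
      if (is.null(tr)) return(TRUE) # unstable => failure
      !isTRUE(bh$predicate(tr))
    }, logical(1))
    out <- tibble::tibble(transistor = tid)
    for (b in names(behaviors)) out[[b]] <- hit[[b]]
    out
  })
  nb <- length(behaviors)
  rows$n_disrupted <- rowSums(as.matrix(rows[names(behaviors)]))
  rows$class <- dplyr::case_when(
    rows$n_disrupted == 0 ~ "none",
    rows$n_disrupted == nb ~ "all",
    TRUE ~ "some")
  rows
}
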