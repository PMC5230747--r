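# Independent switch-level settling oracle: plain-R synchronous relaxation
# using igraph connected components, structurally unrelated to the package's
# compiled settling loop. Implements the declared semantics: conduction from
# gate values (with lesions), wire groups through conducting channels, group
# precedence ground > power > pinned input (low dominant) > pullup > charge
# retention, rails and pinned inputs keep their driven values.

oracle_settle <- function(nl, wire, pinned, lesions = NULL,
                          max_passes = 100 * nrow(nl$wires)) {
  w <- nl$wires
  tr <- nl$transistors
  widx <- function(ids) match(ids, w$id)
  g <- widx(tr$gate)
  c1 <- widx(tr$c1)
  c2 <- widx(tr$c2)
  les <- rep(0L, nrow(tr))
  if (!is.null(lesions) && nrow(lesions)) {
    les[match(lesions$transistor, tr$id)] <-
      ifelse(lesions$mode == "stuck_on", 1L, 2L)
  }
  pw <- widx(w$id[w$role == "power"])
  gd <- widx(w$id[w$role == "ground"])
  nw <- nrow(w)
  for (pass in seq_len(max_passes)) {
    on <- ifelse(les == 1L, TRUE, ifelse(les == 2L, FALSE, wire[g] == 1L))
    memb <- if (any(on)) {
      gr <- igraph::graph_from_edgelist(cbind(c1[on], c2[on]),
                                        directed = FALSE)
      gr <- igraph::add_vertices(gr, max(0, nw - igraph::vcount(gr)))
      igraph::components(gr)$membership
    } else seq_len(nw)
    val <- integer(nw)
    for (comp in unique(memb)) {
      ix <- which(memb == comp)
      val[ix] <- if (gd %in% ix) 0L
      else if (pw %in% ix) 1L
      else if (any(pinned[ix] == 0L, na.rm = TRUE)) 0L
      else if (any(pinned[ix] == 1L, na.rm = TRUE)) 1L
      else if (any(w$pullup[ix])) 1L
      else if (any(wire[ix] == 1L)) 1L
      else 0L
    }
    val[pw] <- 1L
    val[gd] <- 0L
    val[!is.na(pinned)] <- pinned[!is.na(pinned)]
    if (all(val == wire)) {
      on <- ifelse(les == 1L, TRUE, ifelse(les == 2L, FALSE, val[g] == 1L))
      return(list(stable = TRUE, wire = val, on = as.integer(on)))
    }
    wire <- val
  }
  list(stable = FALSE, wire = wire)
}

# full run: all-low initial state, inputs pinned to the stimulus each step
oracle_run <- function(nl, stim, lesions = NULL) {
  w <- nl$wires
  nw <- nrow(w)
  wire <- integer(nw)
  wire[w$role == "power"] <- 1L
  pinned <- rep(NA_integer_, nw)
  in_idx <- match(wire_id(nl, colnames(stim)), w$id)
  wv <- matrix(NA_integer_, nrow(stim), nw)
  tv <- matrix(NA_integer_, nrow(stim), nrow(nl$transistors))
  for (t in seq_len(nrow(stim))) {
    pinned[in_idx] <- as.integer(stim[t, ])
    wire[in_idx] <- as.integer(stim[t, ])
    res <- oracle_settle(nl, wire, pinned, lesions)
    if (!res$stable) return(list(stable = FALSE, timestep = t))
    wire <- res$wire
    wv[t, ] <- wire
    tv[t, ] <- res$on
  }
  list(stable = TRUE, wire_values = wv, transistor_on = tv)
}

# random small netlist: rails, two inputs, a handful of plain wires with
# random pullups, and transistors with random terminals (c1 != c2)
random_netlist <- function(n_plain = 8, n_transistors = 12, seed = 1) {
  silicophys:::withr_seed(seed, {
    roles <- c("power", "ground", "input", "input", rep("plain", n_plain))
    wires <- tibble::tibble(
      id = seq_along(roles) - 1L,
      name = c("vcc", "vss", "in1", "in2", paste0("w", seq_len(n_plain))),
      pullup = c(FALSE, FALSE, FALSE, FALSE,
                 stats::runif(n_plain) < 0.4),
      role = roles)
    n_w <- nrow(wires)
    tr <- tibble::tibble(
      id = seq_len(n_transistors) - 1L,
      gate = sample(wires$id, n_transistors, replace = TRUE),
      c1 = sample(wires$id, n_transistors, replace = TRUE),
      c2 = sample(wires$id, n_transistors, replace = TRUE),
      x = stats::runif(n_transistors, 0, 100),
      y = stats::runif(n_transistors, 0, 100))
    clash <- tr$c1 == tr$c2
    tr$c2[clash] <- (tr$c1[clash] + 1L) %% n_w
    netlist(wires, tr)
  })
}

random_stimulus <- function(nl, n_steps = 4, seed = 1) {
  silicophys:::withr_seed(seed, {
    m <- matrix(sample(0:1, 2 * n_steps, replace = TRUE), ncol = 2)
    colnames(m) <- c("in1", "in2")
    stimulus_program(nl, m)
  })
}
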