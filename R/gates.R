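#' Append a logic gate to a netlist
#'
#' Builds standard NMOS pullup/pulldown gates out of enhancement-mode
#' transistors. Static gates (`not`, `nand2`, `nand3`, `nor2`, and the
#' derived `and2`, `and3`, `xor2`) drive their output through a depletion
#' pullup plus a pulldown network to ground. `pass_latch` is a
#' transmission-gate latch: a pass transistor into a charge-storage node
#' followed by two inverters (the node retains its value while the clock is
#' low). `dff_2phase` chains two pass latches clocked on opposite phases of
#' a two-phase clock (master-slave flip-flop).
#'
#' @param nl a `netlist`.
#' @param kind one of `"not"`, `"nand2"`, `"nand3"`, `"nor2"`, `"and2"`,
#'   `"and3"`, `"xor2"`, `"pass_latch"`, `"dff_2phase"`.
#' @param inputs character vector of input wire names (for `pass_latch`:
#'   `c(data, clock)`; for `dff_2phase`: `c(data, clk0, clk1)`).
#' @param output output wire name; the wire must already exist. For static
#'   gates it is given a pullup.
#' @param at length-2 numeric, layout position of the gate.
#' @return the extended `netlist`; the attribute `"last_ids"` holds the ids
#'   of the transistors just added (useful for module annotation).
#' @export
add_gate <- function(nl, kind, inputs, output, at = c(0, 0)) {
  out_role <- nl$wires$role[match(resolve_wire(nl, output), nl$wires$id)]
  if (out_role %in% c("power", "ground")) {
    stop("cannot drive power/ground wire: ", output)
  }
  first_new <- if (nrow(nl$transistors)) max(nl$transistors$id) + 1L else 0L
  nl <- build_gate_impl(nl, kind, inputs, output, at)
  last <- max(nl$transistors$id)
  attr(nl, "last_ids") <- seq.int(first_new, last)
  nl
}

# internal wire names are derived from the output name and current max id,
# which keeps them unique within one growing netlist
fresh_name <- function(nl, base, suffix) {
  sprintf("%s.%s%d", base, suffix, max(nl$wires$id) + 1L)
}

set_pullup <- function(nl, wire) {
  nl$wires$pullup[match(resolve_wire(nl, wire), nl$wires$id)] <- TRUE
  nl
}

place <- function(at, k) c(at[1] + (k %% 4) * 4, at[2] + (k %/% 4) * 4)

build_gate_impl <- function(nl, kind, inputs, output, at) {
  gnd <- ground_id(nl)
  switch(
    kind,
    "not" = {
      stopifnot(length(inputs) == 1)
      nl <- set_pullup(nl, output)
      p <- place(at, 0)
      add_transistor(nl, inputs[1], output, gnd, p[1], p[2])
    },
    "nand2" = {
      stopifnot(length(inputs) == 2)
      nl <- set_pullup(nl, output)
      mid <- fresh_name(nl, output, "m")
      nl <- add_wire(nl, mid)
      p1 <- place(at, 0); p2 <- place(at, 1)
      nl <- add_transistor(nl, inputs[1], output, mid, p1[1], p1[2])
      add_transistor(nl, inputs[2], mid, gnd, p2[1], p2[2])
    },
    "nand3" = {
      stopifnot(length(inputs) == 3)
      nl <- set_pullup(nl, output)
      m1 <- fresh_name(nl, output, "m")
      nl <- add_wire(nl, m1)
      m2 <- fresh_name(nl, output, "m")
      nl <- add_wire(nl, m2)
      p1 <- place(at, 0); p2 <- place(at, 1); p3 <- place(at, 2)
      nl <- add_transistor(nl, inputs[1], output, m1, p1[1], p1[2])
      nl <- add_transistor(nl, inputs[2], m1, m2, p2[1], p2[2])
      add_transistor(nl, inputs[3], m2, gnd, p3[1], p3[2])
    },
    "nor2" = {
      stopifnot(length(inputs) == 2)
      nl <- set_pullup(nl, output)
      p1 <- place(at, 0); p2 <- place(at, 1)
      nl <- add_transistor(nl, inputs[1], output, gnd, p1[1], p1[2])
      add_transistor(nl, inputs[2], output, gnd, p2[1], p2[2])
    },
    "and2" = {
      nb <- fresh_name(nl, output, "nb")
      nl <- add_wire(nl, nb)
      nl <- build_gate_impl(nl, "nand2", inputs, nb, at)
      build_gate_impl(nl, "not", nb, output, at + c(0, 8))
    },
    "and3" = {
      nb <- fresh_name(nl, output, "nb")
      nl <- add_wire(nl, nb)
      nl <- build_gate_impl(nl, "nand3", inputs, nb, at)
      build_gate_impl(nl, "not", nb, output, at + c(0, 8))
    },
    "xor2" = {
      stopifnot(length(inputs) == 2)
      wn <- fresh_name(nl, output, "xn"); nl <- add_wire(nl, wn)
      wa <- fresh_name(nl, output, "xa"); nl <- add_wire(nl, wa)
      wr <- fresh_name(nl, output, "xr"); nl <- add_wire(nl, wr)
      nl <- build_gate_impl(nl, "nand2", inputs, wn, at)
      nl <- build_gate_impl(nl, "not", wn, wa, at + c(8, 0))
      nl <- build_gate_impl(nl, "nor2", inputs, wr, at + c(0, 8))
      build_gate_impl(nl, "nor2", c(wr, wa), output, at + c(8, 8))
    },
    "pass_latch" = {
      stopifnot(length(inputs) == 2) # data, clock
      s <- fresh_name(nl, output, "s")
      nl <- add_wire(nl, s) # storage node, no pullup: retains charge
      sb <- fresh_name(nl, output, "sb")
      nl <- add_wire(nl, sb)
      p <- place(at, 0)
      nl <- add_transistor(nl, inputs[2], inputs[1], s, p[1], p[2])
      nl <- build_gate_impl(nl, "not", s, sb, at + c(4, 0))
      build_gate_impl(nl, "not", sb, output, at + c(8, 0))
    },
    "dff_2phase" = {
      stopifnot(length(inputs) == 3) # data, clk0, clk1
      m <- fresh_name(nl, output, "q")
      nl <- add_wire(nl, m)
      nl <- build_gate_impl(nl, "pass_latch", c(inputs[1], inputs[2]), m, at)
      build_gate_impl(nl, "pass_latch", c(m, inputs[3]), output, at + c(0, 8))
    },
    stop("unknown gate kind: ", kind))
}

#' Compose netlist fragments into one validated netlist
#'
#' Fragments share a wire namespace: wires with the same name are unified
#' (their `pullup`/`role` attributes must agree), unnamed wires stay
#' distinct, and the power/ground rails of all fragments collapse into one
#' pair. Wire and transistor ids are renumbered consecutively; signals and
#' module annotations are carried over (module labels occurring in several
#' fragments are unioned).
#'
#' @param ... `netlist` fragments. With no arguments, returns the minimal
#'   valid netlist (power and ground only).
#' @return a validated `netlist`.
#' @export
compose <- function(...) {
  frags <- list(...)
  if (length(frags) == 0) return(empty_netlist())
  for (f in frags) stopifnot(inherits(f, "netlist"))

  wires <- tibble::tibble(id = integer(), name = character(),
                          pullup = logical(), role = character())
  next_id <- 0L
  maps <- vector("list", length(frags))
  for (i in seq_along(frags)) {
    fw <- frags[[i]]$wires
    map <- integer(max(fw$id) + 1L)
    for (j in seq_len(nrow(fw))) {
      nm <- fw$name[j]
      hit <- if (!is.na(nm)) match(nm, wires$name) else NA_integer_
      if (!is.na(hit)) {
        if (wires$pullup[hit] != fw$pullup[j] || wires$role[hit] != fw$role[j]) {
          stop("wire attribute collision on shared wire: ", nm)
        }
        map[fw$id[j] + 1L] <- wires$id[hit]
      } else {
        wires <- dplyr::bind_rows(
          wires, tibble::tibble(id = next_id, name = nm,
                                pullup = fw$pullup[j], role = fw$role[j]))
        map[fw$id[j] + 1L] <- next_id
        next_id <- next_id + 1L
      }
    }
    maps[[i]] <- map
  }

  trs <- list()
  sigs <- list()
  mods <- list()
  next_tid <- 0L
  for (i in seq_along(frags)) {
    ft <- frags[[i]]$transistors
    map <- maps[[i]]
    tmap <- integer(if (nrow(ft)) max(ft$id) + 1L else 0L)
    if (nrow(ft)) {
      new_ids <- seq.int(next_tid, next_tid + nrow(ft) - 1L)
      tmap[ft$id + 1L] <- new_ids
      trs[[i]] <- tibble::tibble(
        id = new_ids, gate = map[ft$gate + 1L],
        c1 = map[ft$c1 + 1L], c2 = map[ft$c2 + 1L], x = ft$x, y = ft$y)
      next_tid <- next_tid + nrow(ft)
    }
    for (s in names(frags[[i]]$signals)) {
      v <- map[frags[[i]]$signals[[s]] + 1L]
      if (!is.null(sigs[[s]]) && sigs[[s]] != v) {
        stop("signal name collision with different wires: ", s)
      }
      sigs[[s]] <- v
    }
    for (m in names(frags[[i]]$modules)) {
      mods[[m]] <- sort(unique(c(mods[[m]], tmap[frags[[i]]$modules[[m]] + 1L])))
    }
  }
  netlist(wires, dplyr::bind_rows(trs), sigs, mods)
}
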