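#' Construct a transistor netlist
#'
#' A netlist is the circuit's "connectome": a table of wires, a table of
#' three-terminal enhancement-mode transistors, a map of named control
#' signals to wire ids, and a map of functional module labels to transistor
#' id sets (the ground-truth annotation that analyses are scored against).
#'
#' Depletion-mode pullups are modelled as a wire attribute (`pullup`), not as
#' explicit devices: they act as static loads pulling an undriven wire high.
#'
#' @param wires tibble with columns `id` (non-negative integer, unique),
#'   `name` (character, `NA` allowed), `pullup` (logical), `role` (one of
#'   `"plain"`, `"power"`, `"ground"`, `"input"`, `"output"`).
#' @param transistors tibble with columns `id`, `gate`, `c1`, `c2` (wire
#'   ids) and layout coordinates `x`, `y` in abstract micrometres.
#' @param signals named list or vector mapping signal names (e.g. `"CLK0"`)
#'   to wire ids.
#' @param modules named list mapping module labels to integer vectors of
#'   transistor ids; sets may overlap.
#' @return an object of class `netlist`.
#' @export
netlist <- function(wires, transistors, signals = list(), modules = list()) {
  wires <- tibble::as_tibble(wires)
  transistors <- tibble::as_tibble(transistors)
  if (nrow(transistors) == 0) {
    transistors <- tibble::tibble(id = integer(), gate = integer(),
                                  c1 = integer(), c2 = integer(),
                                  x = double(), y = double())
  }
  nl <- structure(
    list(wires = wires[order(wires$id), ],
         transistors = transistors[order(transistors$id), ],
         signals = as.list(signals),
         modules = lapply(modules, function(m) sort(as.integer(m)))),
    class = "netlist")
  validate_netlist(nl)
  nl
}

#' Validate netlist invariants
#'
#' Checks id uniqueness, the single power/ground pair, pullup restrictions,
#' terminal references, and that every signal and module entry resolves.
#' Dangling references raise an error listing the offending ids.
#'
#' @param nl a `netlist`.
#' @return `nl`, invisibly.
#' @export
validate_netlist <- function(nl) {
  w <- nl$wires
  tr <- nl$transistors
  if (anyDuplicated(w$id)) {
    stop("duplicate wire ids: ", paste(w$id[duplicated(w$id)], collapse = ", "))
  }
  if (any(w$id < 0) || any(w$id != floor(w$id))) {
    stop("wire ids must be non-negative integers")
  }
  ok_roles <- c("plain", "power", "ground", "input", "output")
  if (!all(w$role %in% ok_roles)) {
    stop("invalid wire role(s): ",
         paste(unique(setdiff(w$role, ok_roles)), collapse = ", "))
  }
  if (sum(w$role == "power") != 1L || sum(w$role == "ground") != 1L) {
    stop("netlist must have exactly one power and one ground wire")
  }
  if (any(w$pullup & w$role %in% c("power", "ground"))) {
    stop("pullup must be FALSE on power/ground wires")
  }
  if (nrow(tr)) {
    if (anyDuplicated(tr$id)) {
      stop("duplicate transistor ids: ",
           paste(tr$id[duplicated(tr$id)], collapse = ", "))
    }
    refs <- c(tr$gate, tr$c1, tr$c2)
    bad <- sort(unique(refs[!(refs %in% w$id)]))
    if (length(bad)) {
      stop("transistor terminal references missing wire id(s): ",
           paste(bad, collapse = ", "))
    }
    if (any(tr$c1 == tr$c2)) {
      stop("transistor c1 and c2 must differ (transistor id(s) ",
           paste(tr$id[tr$c1 == tr$c2], collapse = ", "), ")")
    }
    if (!all(is.finite(tr$x)) || !all(is.finite(tr$y))) {
      stop("transistor coordinates must be finite")
    }
  }
  sid <- unlist(nl$signals, use.names = FALSE)
  if (length(sid) && !all(sid %in% w$id)) {
    stop("signal(s) reference missing wire id(s): ",
         paste(sort(unique(sid[!(sid %in% w$id)])), collapse = ", "))
  }
  mid <- unlist(nl$modules, use.names = FALSE)
  if (length(mid) && !all(mid %in% tr$id)) {
    stop("module(s) reference missing transistor id(s): ",
         paste(sort(unique(mid[!(mid %in% tr$id)])), collapse = ", "))
  }
  invisible(nl)
}

#' @export
print.netlist <- function(x, ...) {
  cat("<netlist> ", nrow(x$wires), " wires, ", nrow(x$transistors),
      " transistors, ", length(x$signals), " signals, ",
      length(x$modules), " modules\n", sep = "")
  if (length(x$modules)) {
    cat("  modules: ", paste(names(x$modules), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Minimal netlist containing only power and ground
#'
#' Starting point for the builder verbs ([add_wire()], [add_gate()],
#' [add_transistor()]).
#'
#' @param power,ground names for the rails.
#' @return a `netlist` with two wires and no transistors.
#' @export
empty_netlist <- function(power = "vcc", ground = "vss") {
  netlist(
    wires = tibble::tibble(id = c(0L, 1L), name = c(power, ground),
                           pullup = FALSE, role = c("power", "ground")),
    transistors = tibble::tibble(id = integer(), gate = integer(),
                                 c1 = integer(), c2 = integer(),
                                 x = double(), y = double()))
}

#' Look up wire ids by name
#'
#' @param nl a `netlist`.
#' @param name character vector of wire names.
#' @return integer wire ids.
#' @export
wire_id <- function(nl, name) {
  idx <- match(name, nl$wires$name)
  if (anyNA(idx)) {
    stop("unknown wire name(s): ", paste(name[is.na(idx)], collapse = ", "))
  }
  nl$wires$id[idx]
}

# resolve a wire reference that may be a name or an id
resolve_wire <- function(nl, ref) {
  if (is.character(ref)) wire_id(nl, ref) else as.integer(ref)
}

#' Add a wire to a netlist
#'
#' @param nl a `netlist`.
#' @param name wire name (must be unique among named wires).
#' @param pullup logical; depletion-mode load attached.
#' @param role wire role.
#' @return the extended `netlist`.
#' @export
add_wire <- function(nl, name, pullup = FALSE, role = "plain") {
  if (!is.na(name) && name %in% nl$wires$name) {
    stop("wire name already in use: ", name)
  }
  id <- if (nrow(nl$wires)) max(nl$wires$id) + 1L else 0L
  nl$wires <- dplyr::bind_rows(
    nl$wires,
    tibble::tibble(id = id, name = name, pullup = pullup, role = role))
  validate_netlist(nl)
}

#' Add a single transistor
#'
#' @param nl a `netlist`.
#' @param gate,c1,c2 wire names or ids.
#' @param x,y layout coordinates (abstract micrometres).
#' @return the extended `netlist`.
#' @export
add_transistor <- function(nl, gate, c1, c2, x = 0, y = 0) {
  id <- if (nrow(nl$transistors)) max(nl$transistors$id) + 1L else 0L
  nl$transistors <- dplyr::bind_rows(
    nl$transistors,
    tibble::tibble(id = id, gate = resolve_wire(nl, gate),
                   c1 = resolve_wire(nl, c1), c2 = resolve_wire(nl, c2),
                   x = as.double(x), y = as.double(y)))
  validate_netlist(nl)
}

power_id <- function(nl) nl$wires$id[nl$wires$role == "power"]
ground_id <- function(nl) nl$wires$id[nl$wires$role == "ground"]

#' Register a named control signal
#' @param nl a `netlist`.
#' @param name signal name, e.g. `"CLK0"`.
#' @param wire wire name or id the signal lives on.
#' @export
add_signal <- function(nl, name, wire) {
  nl$signals[[name]] <- resolve_wire(nl, wire)
  validate_netlist(nl)
}

#' Annotate a functional module
#' @param nl a `netlist`.
#' @param name module label.
#' @param transistor_ids integer ids belonging to the module.
#' @export
add_module <- function(nl, name, transistor_ids) {
  nl$modules[[name]] <- sort(unique(as.integer(
    c(nl$modules[[name]], transistor_ids))))
  validate_netlist(nl)
}
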