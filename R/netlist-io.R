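#' Read a netlist from canonical JSON
#'
#' The on-disk schema is
#' `{"modules":{label:[int]}, "signals":{name:int}, "transistors":[{"c1":int,
#' "c2":int,"gate":int,"id":int,"x":num,"y":num}], "wires":[{"id":int,
#' "name":str|null,"pullup":bool,"role":str}]}` with power and ground
#' identified by `role`. Schema violations raise a parse error naming the
#' offending field; dangling references raise a validation error listing the
#' missing ids.
#'
#' @param path path to a UTF-8 JSON file.
#' @return a validated `netlist`.
#' @export
read_netlist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("wires", "transistors")) {
    if (is.null(doc[[key]])) stop("netlist JSON missing field: ", key)
  }
  need <- function(obj, field, where) {
    if (is.null(obj[[field]])) {
      stop("netlist JSON: missing field '", field, "' in ", where)
    }
    obj[[field]]
  }
  wires <- purrr::map_dfr(doc$wires, function(w) {
    nm <- w$name
    tibble::tibble(
      id = as.integer(need(w, "id", "wire")),
      name = if (is.null(nm)) NA_character_ else as.character(nm),
      pullup = as.logical(need(w, "pullup", "wire")),
      role = as.character(need(w, "role", "wire")))
  })
  transistors <- purrr::map_dfr(doc$transistors, function(t) {
    tibble::tibble(
      id = as.integer(need(t, "id", "transistor")),
      gate = as.integer(need(t, "gate", "transistor")),
      c1 = as.integer(need(t, "c1", "transistor")),
      c2 = as.integer(need(t, "c2", "transistor")),
      x = as.double(need(t, "x", "transistor")),
      y = as.double(need(t, "y", "transistor")))
  })
  signals <- lapply(doc$signals, as.integer)
  modules <- lapply(doc$modules, function(m) as.integer(unlist(m)))
  netlist(wires, transistors, signals, modules)
}

#' Write a netlist in canonical JSON form
#'
#' Canonical form: object keys sorted alphabetically, wire and transistor
#' arrays ordered by id, UTF-8, LF line endings, two-space indentation.
#' `read_netlist()` followed by `write_netlist()` reproduces a canonical
#' file byte-for-byte, which the round-trip tests rely on.
#'
#' @param nl a `netlist`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_netlist <- function(nl, path) {
  validate_netlist(nl)
  w <- nl$wires[order(nl$wires$id), ]
  tr <- nl$transistors[order(nl$transistors$id), ]
  wires <- lapply(seq_len(nrow(w)), function(i) {
    list(id = w$id[i], name = w$name[i],
         pullup = w$pullup[i], role = w$role[i])
  })
  transistors <- lapply(seq_len(nrow(tr)), function(i) {
    list(c1 = tr$c1[i], c2 = tr$c2[i], gate = tr$gate[i], id = tr$id[i],
         x = tr$x[i], y = tr$y[i])
  })
  as_map <- function(x) if (length(x)) x[order(names(x))] else
    stats::setNames(list(), character())
  sigs <- as_map(nl$signals)
  mods <- as_map(lapply(nl$modules, sort))
  doc <- list(modules = mods, signals = sigs,
              transistors = transistors, wires = wires)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2,
                           null = "null", na = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
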