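test_that("shipped fixture files load, validate, and round-trip byte-exactly", {
  for (f in c("inverter.json", "nand.json")) {
    path <- system.file("extdata", f, package = "silicophys")
    nl <- read_netlist(path)
    expect_s3_class(nl, "netlist")
    out <- withr::local_tempfile(fileext = ".json")
    write_netlist(nl, out)
    expect_identical(readBin(out, "raw", file.size(out)),
                     readBin(path, "raw", file.size(path)))
  }
  inv <- read_netlist(system.file("extdata", "inverter.json",
                                  package = "silicophys"))
  expect_equal(nrow(inv$transistors), 1L)
  expect_true(inv$wires$pullup[inv$wires$name == "out"])
})

test_that("read-write-read is the identity on random small netlists", {
  for (s in 1:10) {
    nl <- random_netlist(seed = s)
    p1 <- withr::local_tempfile(fileext = ".json")
    p2 <- withr::local_tempfile(fileext = ".json")
    write_netlist(nl, p1)
    nl2 <- read_netlist(p1)
    write_netlist(nl2, p2)
    expect_identical(readLines(p1), readLines(p2))
    expect_equal(nl2$wires, nl$wires)
    expect_equal(nl2$transistors, nl$transistors)
  }
})

test_that("dangling references and schema violations are reported by id/field", {
  wires <- tibble::tibble(id = 0:1, name = c("vcc", "vss"),
                          pullup = FALSE, role = c("power", "ground"))
  tr <- tibble::tibble(id = 0L, gate = 99L, c1 = 0L, c2 = 1L, x = 0, y = 0)
  expect_error(netlist(wires, tr), "99")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"wires":[{"id":0,"name":"vcc","role":"power"},',
                    '{"id":1,"name":"vss","pullup":false,"role":"ground"}],',
                    '"transistors":[]}'), bad)
  expect_error(read_netlist(bad), "pullup")
  expect_error(read_netlist(withr::local_tempfile(fileext = ".json")),
               "no such file")
})

test_that("netlist invariants are enforced", {
  nl <- empty_netlist()
  expect_error(add_wire(nl, "vcc"), "in use")
  w2 <- nl$wires
  w2$role <- c("power", "power")
  expect_error(netlist(w2, nl$transistors), "exactly one")
  w3 <- nl$wires
  w3$pullup <- c(TRUE, FALSE)
  expect_error(netlist(w3, nl$transistors), "pullup")
  tr <- tibble::tibble(id = 0L, gate = 0L, c1 = 1L, c2 = 1L, x = 0, y = 0)
  expect_error(netlist(nl$wires, tr), "c1 and c2")
})

test_that("gate builder emits canonical NMOS structures that validate", {
  nl <- inverter_netlist()
  expect_equal(nrow(nl$transistors), 1L)
  expect_true(nl$wires$pullup[nl$wires$name == "out"])

  nd <- nand_netlist()
  expect_equal(nrow(nd$transistors), 2L)
  # two pulldowns in series: out - mid - ground
  tr <- nd$transistors
  gnd <- nd$wires$id[nd$wires$role == "ground"]
  out <- wire_id(nd, "out")
  expect_true(any(tr$c1 == out))
  expect_true(any(tr$c2 == gnd))
  shared <- intersect(tr$c2[tr$c1 == out], tr$c1[tr$c2 == gnd])
  expect_length(shared, 1)

  expect_error(add_gate(nand_netlist(), "not", "a", "vss"), "ground")
  expect_error(add_gate(nand_netlist(), "frob", "a", "out"), "unknown")
  for (kind in c("nor2", "xor2", "and2")) {
    nl2 <- add_gate(nand_netlist(), kind, c("a", "b"), "out")
    expect_silent(validate_netlist(nl2))
  }
})

test_that("compose merges fragments by wire name and renumbers", {
  expect_equal(nrow(compose()$wires), 2L) # minimal valid netlist

  f1 <- empty_netlist()
  f1 <- add_wire(f1, "in", role = "input")
  f1 <- add_wire(f1, "mid")
  f1 <- add_gate(f1, "not", "in", "mid")
  f2 <- empty_netlist()
  f2 <- add_wire(f2, "mid")
  f2 <- add_wire(f2, "out", role = "output")
  f2 <- add_gate(f2, "not", "mid", "out")
  expect_error(compose(f1, f2), "collision") # mid pullup differs by fragment

  f2b <- empty_netlist()
  f2b <- add_wire(f2b, "mid", pullup = TRUE)
  f2b <- add_wire(f2b, "out", role = "output")
  f2b <- add_gate(f2b, "not", "mid", "out")
  buf <- compose(f1, f2b)
  expect_equal(nrow(buf$transistors), 2L)
  expect_equal(buf$wires$id, seq_len(nrow(buf$wires)) - 1L)
  # the buffer simulates as identity after one settle
  stim <- stimulus_program(buf, matrix(c(0L, 1L, 0L), ncol = 1,
                                       dimnames = list(NULL, "in")))
  tr <- run_trace(buf, stim)
  expect_equal(unname(tr$wire_values[, as.character(wire_id(buf, "out"))]),
               c(0L, 1L, 0L))
})
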