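# small circuits shared across tests, built fresh in code

inverter_netlist <- function() {
  nl <- empty_netlist()
  nl <- add_wire(nl, "in", role = "input")
  nl <- add_wire(nl, "out", role = "output")
  add_gate(nl, "not", "in", "out")
}

nand_netlist <- function() {
  nl <- empty_netlist()
  nl <- add_wire(nl, "a", role = "input")
  nl <- add_wire(nl, "b", role = "input")
  nl <- add_wire(nl, "out", role = "output")
  add_gate(nl, "nand2", c("a", "b"), "out")
}

# one-bit full adder with driven inputs, via the package's ripple-adder cell
adder1_netlist <- function() {
  nl <- empty_netlist()
  for (w in c("a", "b", "cin")) nl <- add_wire(nl, w, role = "input")
  for (w in c("s", "cout")) nl <- add_wire(nl, w, role = "output")
  silicophys:::add_full_adder(nl, "a", "b", "cin", "s", "cout",
                              at = c(0, 0), module = "fa")
}

# four-stage two-phase shift register
shift4_netlist <- function() {
  nl <- empty_netlist()
  for (w in c("clk0", "clk1", "sin")) nl <- add_wire(nl, w, role = "input")
  qs <- paste0("q", 0:3)
  for (q in qs) nl <- add_wire(nl, q)
  din <- c("sin", qs[1:3])
  for (i in 0:3) {
    nl <- add_gate(nl, "dff_2phase", c(din[i + 1], "clk0", "clk1"),
                   qs[i + 1])
  }
  for (q in qs) nl <- add_signal(nl, toupper(q), q)
  nl
}

int_bits <- function(v, n) vapply(0:(n - 1), function(k) (v %/% 2^k) %% 2,
                                  numeric(length(v)))
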