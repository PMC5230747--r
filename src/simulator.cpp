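#include <Rcpp.h>
using namespace Rcpp;

// Switch-level settling core.
//
// Semantics (synchronous relaxation):
//  - a transistor conducts iff its gate wire is high, unless lesioned
//    (stuck_on forces conduction, stuck_off forbids it);
//  - wires connected through the channels (c1-c2) of conducting transistors
//    form a group; the group's value is decided by precedence:
//      contains ground -> low; else contains power -> high;
//      else contains an externally pinned (input) wire -> the pinned value,
//      low dominating on conflict;
//      else any member has a pullup -> high;
//      else any member was high at the start of the pass -> high (charge
//      retention); else low;
//  - power, ground and pinned input wires keep their driven values
//    regardless of grouping;
//  - passes repeat until no wire changes; exceeding the pass cap means the
//    circuit does not settle (oscillation), reported to the caller.

namespace {

struct DSU {
  std::vector<int> parent;
  void init(int n) {
    parent.resize(n);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[a] = b;
  }
};

// One settling run. wire values and transistor states are modified in place.
// Returns number of passes used, or -1 if the pass cap was exceeded (in which
// case `changed_last` marks the wires still flapping).
// pinned: -1 free wire, 0 pinned low, 1 pinned high (externally driven)
int settle(const IntegerVector& gate, const IntegerVector& c1,
           const IntegerVector& c2, const LogicalVector& pullup,
           int power, int ground, const IntegerVector& lesion,
           const std::vector<int>& pinned,
           std::vector<int>& wire, std::vector<int>& ton,
           int max_passes, std::vector<int>& changed_last, DSU& dsu) {
  const int nt = gate.size();
  const int nw = wire.size();
  std::vector<int> new_wire(nw);

  for (int pass = 1; pass <= max_passes; ++pass) {
    // conduction from current gate values (+ lesions)
    for (int t = 0; t < nt; ++t) {
      int on = wire[gate[t]];
      if (lesion[t] == 1) on = 1;
      else if (lesion[t] == 2) on = 0;
      ton[t] = on;
    }
    // wire groups through conducting channels
    dsu.init(nw);
    for (int t = 0; t < nt; ++t)
      if (ton[t]) dsu.unite(c1[t], c2[t]);
    // group flags: bits: 1 ground, 2 power, 4 pinned-low, 8 pinned-high,
    // 16 pullup, 32 prev-high
    std::vector<int> flags(nw, 0);
    for (int w = 0; w < nw; ++w) {
      int r = dsu.find(w);
      if (w == ground) flags[r] |= 1;
      if (w == power) flags[r] |= 2;
      if (pinned[w] == 0) flags[r] |= 4;
      if (pinned[w] == 1) flags[r] |= 8;
      if (pullup[w]) flags[r] |= 16;
      if (wire[w]) flags[r] |= 32;
    }
    for (int w = 0; w < nw; ++w) {
      int f = flags[dsu.find(w)];
      int v;
      if (f & 1) v = 0;
      else if (f & 2) v = 1;
      else if (f & 4) v = 0;
      else if (f & 8) v = 1;
      else if (f & 16) v = 1;
      else if (f & 32) v = 1;
      else v = 0;
      new_wire[w] = v;
    }
    new_wire[power] = 1;
    new_wire[ground] = 0;
    for (int w = 0; w < nw; ++w)
      if (pinned[w] >= 0) new_wire[w] = pinned[w];

    bool any = false;
    changed_last.clear();
    for (int w = 0; w < nw; ++w) {
      if (new_wire[w] != wire[w]) {
        any = true;
        changed_last.push_back(w);
      }
      wire[w] = new_wire[w];
    }
    if (!any) {
      // final conduction states consistent with settled wires
      for (int t = 0; t < nt; ++t) {
        int on = wire[gate[t]];
        if (lesion[t] == 1) on = 1;
        else if (lesion[t] == 2) on = 0;
        ton[t] = on;
      }
      return pass;
    }
  }
  return -1;
}

} // namespace

// [[Rcpp::export]]
List settle_cpp(IntegerVector gate, IntegerVector c1, IntegerVector c2,
                LogicalVector pullup, int power, int ground,
                IntegerVector wire_init, IntegerVector lesion,
                IntegerVector pinned_in, int max_passes) {
  std::vector<int> wire(wire_init.begin(), wire_init.end());
  std::vector<int> pinned(pinned_in.begin(), pinned_in.end());
  std::vector<int> ton(gate.size(), 0);
  std::vector<int> changed;
  DSU dsu;
  int passes = settle(gate, c1, c2, pullup, power, ground, lesion, pinned,
                      wire, ton, max_passes, changed, dsu);
  return List::create(
      _["wire"] = IntegerVector(wire.begin(), wire.end()),
      _["ton"] = IntegerVector(ton.begin(), ton.end()),
      _["stable"] = passes > 0,
      _["passes"] = passes,
      _["oscillating"] = IntegerVector(changed.begin(), changed.end()));
}

// Run a stimulus program: at each timestep assign the input wires, settle,
// and record the fixed-point state. stim is T x n_inputs (0/1).
// [[Rcpp::export]]
List run_cpp(IntegerVector gate, IntegerVector c1, IntegerVector c2,
             LogicalVector pullup, int power, int ground,
             IntegerVector input_wires, IntegerMatrix stim,
             IntegerVector lesion, int max_passes) {
  const int T = stim.nrow();
  const int nw = pullup.size();
  const int nt = gate.size();
  std::vector<int> wire(nw, 0);
  wire[power] = 1;
  std::vector<int> ton(nt, 0);
  std::vector<int> changed;
  std::vector<int> pinned(nw, -1);
  DSU dsu;

  IntegerMatrix wv(T, nw);
  IntegerMatrix tv(T, nt);
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < input_wires.size(); ++j) {
      wire[input_wires[j]] = stim(t, j);
      pinned[input_wires[j]] = stim(t, j);
    }
    int passes = settle(gate, c1, c2, pullup, power, ground, lesion, pinned,
                        wire, ton, max_passes, changed, dsu);
    if (passes < 0) {
      return List::create(
          _["stable"] = false, _["timestep"] = t + 1,
          _["oscillating"] = IntegerVector(changed.begin(), changed.end()));
    }
    for (int w = 0; w < nw; ++w) wv(t, w) = wire[w];
    for (int k = 0; k < nt; ++k) tv(t, k) = ton[k];
  }
  return List::create(_["stable"] = true, _["wire_values"] = wv,
                      _["transistor_on"] = tv);
}
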