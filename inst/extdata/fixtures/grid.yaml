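# 3x3 lattice, equal populations, rook adjacency; spatially non-tree-like.
# Layout (row-major):  A B C / D E F / G H I, E central.  The lattice spacing
# keeps neighbor coupling loose enough that local innovations survive and mix.
nodes:
  - {id: A, population: 1.0}
  - {id: B, population: 1.0}
  - {id: C, population: 1.0}
  - {id: D, population: 1.0}
  - {id: E, population: 1.0}
  - {id: F, population: 1.0}
  - {id: G, population: 1.0}
  - {id: H, population: 1.0}
  - {id: I, population: 1.0}
edges:
  - {i: A, j: B, distance: 1.4}
  - {i: B, j: C, distance: 1.4}
  - {i: D, j: E, distance: 1.4}
  - {i: E, j: F, distance: 1.4}
  - {i: G, j: H, distance: 1.4}
  - {i: H, j: I, distance: 1.4}
  - {i: A, j: D, distance: 1.4}
  - {i: D, j: G, distance: 1.4}
  - {i: B, j: E, distance: 1.4}
  - {i: E, j: H, distance: 1.4}
  - {i: C, j: F, distance: 1.4}
  - {i: F, j: I, distance: 1.4}
params: {s: 4.0, b: 1.0, d: 3.0, T: 1000, n_concepts: 100}
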