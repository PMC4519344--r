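# Two centers (A, B) with four exclusive peripheries each, plus two shared
# nodes H and K that are equidistant from both centers.  Center populations
# sit just below the regime where center-driven innovation churns the whole
# network.
nodes:
  - {id: A, population: 8.0}
  - {id: B, population: 8.0}
  - {id: C, population: 1.0}
  - {id: D, population: 1.0}
  - {id: E, population: 1.0}
  - {id: F, population: 1.0}
  - {id: G, population: 1.0}
  - {id: H, population: 1.0}
  - {id: I, population: 1.0}
  - {id: J, population: 1.0}
  - {id: K, population: 1.0}
  - {id: L, population: 1.0}
edges:
  - {i: A, j: B, distance: 2.0}
  - {i: A, j: C, distance: 1.0}
  - {i: A, j: D, distance: 1.0}
  - {i: A, j: E, distance: 1.0}
  - {i: A, j: F, distance: 1.0}
  - {i: B, j: G, distance: 1.0}
  - {i: B, j: I, distance: 1.0}
  - {i: B, j: J, distance: 1.0}
  - {i: B, j: L, distance: 1.0}
  - {i: A, j: H, distance: 1.0}
  - {i: B, j: H, distance: 1.0}
  - {i: A, j: K, distance: 1.0}
  - {i: B, j: K, distance: 1.0}
params: {s: 2.0, b: 1.0, d: 3.0, T: 1000, n_concepts: 100}
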