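# Two internally well-connected dialect clusters -- a western ring A-E with
# two stabilizing chords and an eastern triangle F-G-H -- joined by one long
# bridge edge E-F; E is the western bridgehead.
nodes:
  - {id: A, population: 1.0}
  - {id: B, population: 1.0}
  - {id: C, population: 1.0}
  - {id: D, population: 1.0}
  - {id: E, population: 1.0}
  - {id: F, population: 1.0}
  - {id: G, population: 1.0}
  - {id: H, population: 1.0}
edges:
  - {i: A, j: B, distance: 1.0}
  - {i: B, j: C, distance: 1.0}
  - {i: C, j: D, distance: 1.0}
  - {i: D, j: E, distance: 1.0}
  - {i: E, j: A, distance: 1.0}
  - {i: A, j: C, distance: 1.15}
  - {i: B, j: D, distance: 1.15}
  - {i: F, j: G, distance: 1.0}
  - {i: G, j: H, distance: 1.0}
  - {i: F, j: H, distance: 1.0}
  - {i: E, j: F, distance: 3.0}
params: {s: 4.0, b: 0.1, d: 3.0, T: 1000, n_concepts: 100}
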