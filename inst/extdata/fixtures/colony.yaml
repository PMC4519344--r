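# Bottleneck-style ten-node network (west ring A,C,D,E,F; east ring
# G,H,I,J,K) that runs 750 steps without node B.  At the end of step 750
# node B is created as an exact copy of western node A -- a large colony of
# the western dialect group in the east -- and evolves for the remaining 250
# steps.  B's links into the eastern cluster are long, so its conversion of
# the eastern lexicon stays partial within those 250 steps; the loose ring
# spacing keeps both clusters internally diverse.
nodes:
  - {id: A, population: 1.0}
  - {id: B, population: 10.0}
  - {id: C, population: 1.0}
  - {id: D, population: 1.0}
  - {id: E, population: 1.0}
  - {id: F, population: 1.0}
  - {id: G, population: 1.0}
  - {id: H, population: 1.0}
  - {id: I, population: 1.0}
  - {id: J, population: 1.0}
  - {id: K, population: 1.0}
edges:
  - {i: A, j: C, distance: 2.2}
  - {i: C, j: D, distance: 2.2}
  - {i: D, j: E, distance: 2.2}
  - {i: E, j: F, distance: 2.2}
  - {i: F, j: A, distance: 2.2}
  - {i: G, j: H, distance: 2.2}
  - {i: H, j: I, distance: 2.2}
  - {i: I, j: J, distance: 2.2}
  - {i: J, j: K, distance: 2.2}
  - {i: K, j: G, distance: 2.2}
  - {i: F, j: G, distance: 2.0}
  - {i: B, j: G, distance: 6.0}
  - {i: B, j: H, distance: 6.0}
  - {i: B, j: I, distance: 6.0}
  - {i: B, j: J, distance: 6.0}
  - {i: B, j: K, distance: 6.0}
events:
  - {time: 750, kind: copy_node, source: A, target: B}
params: {s: 4.0, b: 0.1, d: 3.0, T: 1000, n_concepts: 100}
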