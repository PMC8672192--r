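experiment: removal
model: sir
topology: ba
n_nodes: 2500
er_edges: 312500
ws_k: 250
ws_rewire_prob: 0.1
ba_m: 132
n_graphs: 20
n_inits: 10
beta: 0.001
gamma: 0.01
init_frac: 0.05
max_iters: 2500
final_node_count: 125
n_batches: 35
initial_bulk_removal: 1250
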