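experiment: removal
model: threshold
topology: er
n_nodes: 2500
er_edges: 312500
ws_k: 250
ws_rewire_prob: 0.1
ba_m: 132
n_graphs: 20
n_inits: 10
threshold: 0.5
init_frac: 0.36
max_iters: 30
final_node_count: 125
n_batches: 50
initial_bulk_removal: 0
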