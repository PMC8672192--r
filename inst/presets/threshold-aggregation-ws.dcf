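experiment: aggregation
model: threshold
topology: ws
n_nodes: 2500
ws_k: 250
ws_rewire_prob: 0.1
ba_m: 132
n_graphs: 20
n_inits: 10
threshold: 0.5
init_frac: 0.42
max_iters: 30
alpha: 4
n_bins: 50
shared_threshold: 0.8
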