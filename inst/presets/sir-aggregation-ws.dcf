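experiment: aggregation
model: sir
topology: ws
n_nodes: 2500
ws_k: 250
ws_rewire_prob: 0.1
ba_m: 132
n_graphs: 20
n_inits: 10
beta: 0.001
gamma: 0.2
init_frac: 0.05
max_iters: 2500
alpha: 4
n_bins: 50
shared_threshold: 0.8
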