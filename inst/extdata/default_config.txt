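# Default glomerular-layer configuration (calibrated; see the methods
# vignette for the calibration rationale).  Weights are pA per
# presynaptic spike unless noted.
n_glomeruli 16
cells_per_type 1
# swept inter-glomerular short-axon weight, arbitrary units
sa_weight 19
# pA per arbitrary unit of sa_weight
sa_scale 1
# dimensionless gains on the ORN input current
w_orn_mc 1
w_orn_et 0.8
w_orn_pg 0.2
# fixed intra-glomerular weights, pA per spike
w_mc_pg 10
w_pg_mc 250
w_et_pg 10
w_et_sa 140
# synaptic decay constant, ms
tau_syn 10
# integration step, ms
dt 0.1
# exposure per stimulus, ms
duration 500
# default panel seed
seed 1
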