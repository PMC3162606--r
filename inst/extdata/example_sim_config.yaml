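# Example lattice-model configuration for read_sim_config().
# Units: time in model units (one cycle = 2*pi/omega_mean, mapped to 24 h),
# K dimensionless, D in rad^2 per time unit under the chosen noise scheme.
K: 0.12
N1: 20
N2: 20
NL: 10
sigma_omega: 0.05
gamma: 0.0
D: 0.0
pacemaker_boost: 1.04
dt: 0.02
t_end: 500
transient: 250
seed: 1
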