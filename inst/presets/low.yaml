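# low cargo affinity + avidity: condensates are stabilized on the cargo
# surface (initiation hubs).  Calibrated artifact constants.
dim: 2
box_size: 35
n_particles: 250
particle_radius: 0.5
cargo_radius: 10
eps_AA: 3.5
eps_AC: 0.5
avidity_gain: 1
avidity_cap: 6
r0: 1
a: 6
a_cargo: 3
r_cut: 1.6
r_nb: 1.6
r_bind: 1
D: 1
dt: 0.0004
n_steps: 200000
save_every: 5000
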