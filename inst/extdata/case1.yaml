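# Flat-beam heterogeneous benchmark: a 20 mm diameter, 5 mm deep skin tumor
# uniformly loaded with gold nanorods, embedded in healthy tissue
# (40 mm diameter, 10 mm deep). Optical/thermal values are the package's
# documented reconstruction of this benchmark (absorption-dominated media).
name: case1
length_unit: mm
domain: {r_max: 20, z_max: 10}
mesh: {nr: 122, nz: 62}
default_region: healthy
regions:
  - {label: tumor, r: [0, 10], z: [5, 10]}
optics:
  unit: per_m
  healthy: {mu_a: 30, mu_s: 80, g: 0, "n": 1.37}
  tumor: {mu_a: 800, mu_s: 80, g: 0, "n": 1.37}
thermal:
  healthy: {rho: 1050, cp: 3639, k: 0.5, qm: 420, wb: 0.5, cb: 3840, ta: 37}
  tumor: {rho: 1050, cp: 3639, k: 0.5, qm: 420, wb: 0.5, cb: 3840, ta: 37}
beam: {kind: flat, irradiance: 5000, radius: 10}
boundary:
  optical: {lateral: robin}
  thermal:
    top: {type: convection, h: 10, tref: 25}
    right: {type: dirichlet, value: 37}
    bottom: {type: dirichlet, value: 37}
model: deltap1
run: {dt: 1, duration: 300, t0: 37, seed: 1, photons: 100000}
concentration: {base_region: healthy, loaded_region: tumor}
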