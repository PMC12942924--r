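# Gaussian-beam deep-inclusion phantom: agar gel cylinder (radius 15 mm,
# depth 30 mm) with an embedded gold-nanoparticle-loaded cylinder (radius
# 5 mm, height 10 mm, top face 3 mm below the irradiated surface), Gaussian
# beam FWHM 7 mm / 1.1 W, top-surface convection 5 W K^-1 m^-2, irradiated
# for 706 s. Thermal properties of water; no metabolic or perfusion terms.
name: case2
length_unit: mm
domain: {r_max: 15, z_max: 30}
mesh: {nr: 75, nz: 120}
default_region: gel
regions:
  - {label: gnp, r: [0, 5], z: [17, 27]}
optics:
  unit: per_m
  gel: {mu_a: 2, mu_s: 176, g: 0, "n": 1.33}
  gnp: {mu_a: 31, mu_s: 289, g: 0, "n": 1.33}
thermal:
  gel: {rho: 998, cp: 4182, k: 0.6, qm: 0, wb: 0, cb: 0, ta: 25}
  gnp: {rho: 998, cp: 4182, k: 0.6, qm: 0, wb: 0, cb: 0, ta: 25}
beam: {kind: gaussian, power: 1.1, fwhm: 7}
boundary:
  optical: {lateral: robin}
  thermal:
    top: {type: convection, h: 5, tref: 25}
    right: {type: insulated}
    bottom: {type: insulated}
model: deltap1
run: {dt: 2, duration: 706, t0: 25, seed: 1, photons: 1000000,
      probes: [{r: 0, z: 26}]}
concentration: {base_region: gel, loaded_region: gnp}
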