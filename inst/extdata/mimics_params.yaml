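# Default kinetic configuration for the seven-pool litter/SOM model.
# Rates are hourly; pools mgC cm^-3; temperatures degrees C.
# Every field is read by mimicsParams(); edit here to substitute an
# alternative published configuration.

# Exponential temperature response of the maximum uptake rate:
#   Vmax_j(T) = exp(v_slope * T + v_int) * a_v * v_mod_j * vmax_scale
v_slope: 0.063
v_int: 5.47
a_v: 8.0e-6
# Flux-specific Vmax modifiers, microbes r (copiotroph) and k (oligotroph)
# over substrates m (metabolic litter), s (structural litter), a (available SOM)
v_mod_m: {r: 10.0, k: 3.0}
v_mod_s: {r: 2.0, k: 3.0}
v_mod_a: {r: 10.0, k: 2.0}
# Global catabolic-capacity scaling (0.6 = a 40% reduction of every Vmax)
vmax_scale: 0.6

# Half-saturation constants: Km_j(T) = exp(k_slope_j * T + k_int) * a_k / k_mod_j
k_slope: {m: 0.017, s: 0.027, a: 0.017}
k_int: 3.19
a_k: 10.0
k_mod_m: {r: 8.0, k: 2.0}
k_mod_s: {r: 2.0, k: 4.0}
k_mod_a: {r: 4.0, k: 6.0}
# Texture scalar multiplying k_mod_a: p_scalar_a * exp(p_scalar_b * sqrt(clay))
p_scalar_a: 2.0
p_scalar_b: -2.0
# Km amplifier for oxidation of chemically protected SOM
k_o: {r: 6.0, k: 6.0}

# Carbon-use efficiencies by microbe x substrate class (available SOM uses
# the metabolic-substrate efficiency of each microbe)
cue: {r_m: 0.55, r_s: 0.25, k_m: 0.75, k_s: 0.35}

# Density-dependent turnover: MIC^beta * tau, tau = tau_base * exp(tau_mod * fmet)
tau_base: {r: 5.2e-4, k: 2.4e-4}
tau_mod_r: 0.3
tau_mod_k: 0.1
beta: 1.5

# Turnover partitioning to physically protected SOM: f = a * exp(b * clay)
f_phys_r: [0.3, 1.3]
f_phys_k: [0.2, 0.8]
# ... and to chemically protected SOM: f = a * exp(b * fmet)
f_chem_r: [0.1, -3.0]
f_chem_k: [0.3, -3.0]
# Remainder of turnover goes to available SOM.

# Fraction of litter inputs routed directly to SOM (metabolic -> physically
# protected, structural -> chemically protected)
f_i: {m: 0.05, s: 0.05}

# Desorption of physically protected SOM: d_base * exp(d_clay * clay)
d_base: 1.5e-5
d_clay: -1.5

# Metabolic fraction of litter inputs: clip(f_met0 - f_met_slope * lignin:N)
f_met0: 0.85
f_met_slope: 0.013
f_met_min: 0.01
f_met_max: 0.99

# Unit bridging: bulk-soil depth (cm) converting litterfall gC m^-2 yr^-1
# into a volumetric hourly input
depth_cm: 10.0
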