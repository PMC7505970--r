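# Default model parameters, expressed at microsite scale for system size
# k = 10 (microsite volume k * V = 1e-8 cm^3). The four volume-dependent
# parameters I_C, I_D, K_m and theta are therefore the unit-volume values
# scaled by k (inputs and half-saturation proportional to k, the encounter
# parameter theta inversely proportional). Units: masses mg, times hours.
V: 1.0e-9
k: 10
L: 10
phi: 0.5
gamma_M: 0.3
gamma_Z: 0.4
omega_M: 1.0e-9
omega_Z: 1.0e-16
omega_C: 1.0e-16
omega_D: 1.0e-19
alpha: 1.0e+10
alpha_prime: 2.33e+10
beta: 1.0e+3
rho: 1.0e+3
rho_prime: 1.5e+3
d_M: 2.0e-4
d_Z: 2.0e-3
V_max: 0.42
theta: 7.0e+4
K_m: 3.0e-9
I_C: 5.0e-12
I_D: 0.0
l_C: 1.0e-6
l_D: 1.0e-6
l: 0.0
p: 0.5
T_max: 1.0e+6
p_disp: 0.3
p_open: 0.01
p_mut: 0.1
sigma_mut: 0.05
sigma_diff: 5.0e-6
tau_diff: 1.0
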