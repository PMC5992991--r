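# scaled-down two-population model (80/20 split) in the config dialect
dt: 0.1
tau_rate: 10
populations:
  - name: exc
    kind: excitatory
    size: 48
    params: {C_m: 0.25, V_L: -65, V_thr: -50, V_res: -65, tau_ref: 2, tau_m: 10}
    background_rate: 10
    background_weight: 16.5
  - name: inh
    kind: inhibitory
    size: 12
    params: {C_m: 0.25, V_L: -65, V_thr: -50, V_res: -65, tau_ref: 2, tau_m: 10}
    background_rate: 10
    background_weight: 16.5
elements:
  - {population: exc, element_type: Axon_ex, eta: 0, eps: 5, nu: 1.0e-4}
  - {population: exc, element_type: Den_ex,  eta: 0, eps: 5, nu: 1.0e-4}
  - {population: exc, element_type: Den_in,  eta: 0, eps: 5, nu: -1.0e-4}
  - {population: inh, element_type: Axon_in, eta: 0, eps: 20, nu: -4.0e-4}
  - {population: inh, element_type: Den_ex,  eta: 0, eps: 20, nu: 4.0e-4}
  - {population: inh, element_type: Den_in,  eta: 0, eps: 20, nu: -4.0e-4}
rules:
  - {syn_type: ex, pre_element: Axon_ex, post_element: Den_ex,
     pre_populations: [exc], post_populations: [exc, inh], weight: 187.0}
  - {syn_type: in, pre_element: Axon_in, post_element: Den_in,
     pre_populations: [inh], post_populations: [exc, inh], weight: -187.0}
structural: {update_interval: 100, allow_autapses: false, allow_multapses: true}
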