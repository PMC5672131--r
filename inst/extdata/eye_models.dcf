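name: gullstrand
n_a: 1.0
n_c: 1.376
n_ha: 1.336
e_c_model_mm: 0.5
n_k_classic: 1.3315

name: legrand
n_a: 1.0
n_c: 1.3771
n_ha: 1.3374
e_c_model_mm: 0.55
n_k_classic: 1.3304
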