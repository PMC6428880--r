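{"n_s":3000,"k_1":1,"k_m1":1000,"k_cat":3.6,"k_rev":0.01,"k_c":0.02,"k_tx":0.027,"k_tl":0.2,"k_on":0.0225,"k_off":0.0075,"k_deg":0.2,"delta":0.00025}
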