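# Example run configuration for an ethane-fed batch vessel
# (0.3 l headspace over 0.82 l culture at 35 C).
# Units are part of the key names.
v_gas_l = 0.3
v_liq_l = 0.82
temp_K = 308.15
n_carbons = 2
threshold_mmolN_l = 0.05
ph = 7
seed = 1
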