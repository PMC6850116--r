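key	value
n_probands	105
n_variant_positive	98
n_trios_tested	93
n_de_novo	90
n_inherited	3
n_screened_families	80
n_sperm_donors	51
n_aspcr_informative	33
n_aspcr_paternal	29
n_aspcr_maternal	4
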