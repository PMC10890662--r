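ga_name,ri_pred
GA7,840.94
GA62,685.27
GA88,865.36
GA104,716.94
GA105,535.52
GA106,796.48
GA107,826.57
GA3,653.94
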