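p_sp,p_dp,cardiac_output,heart_rate,myocardial_mass
126,80,4.2,68,142.5
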