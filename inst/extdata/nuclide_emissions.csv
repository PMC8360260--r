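name,kind,energy_MeV,abundance
Cu-64,beta+,0.653,0.178
Cu-64,beta-,0.579,0.385
Cu-64,gamma,0.511,0.352
Lu-177,beta-,0.497,0.786
Lu-177,gamma,0.1129,0.066
Lu-177,gamma,0.2084,0.110
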