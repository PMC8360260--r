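name,half_life_s
Cu-64,45720
Lu-177,578880
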