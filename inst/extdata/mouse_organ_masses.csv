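species,organ,mass_g
mouse,heart,0.15
mouse,lungs,0.20
mouse,stomach,0.50
mouse,pancreas,0.20
mouse,intestine,2.50
mouse,spleen,0.10
mouse,liver,1.50
mouse,kidneys,0.40
mouse,bone,2.80
mouse,skin,4.00
mouse,muscle,11.00
mouse,blood,1.80
mouse,whole_body,30.00
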