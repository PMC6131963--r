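structure,area_um2_min,area_um2_max,strength_MPa_min,strength_MPa_max
ventral_collagen_layer,20000,65000,100,100
septum,6500,7500,100,100
dorsoventral_muscle_bundles,7000,14000,0.2,0.4
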