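alias,canonical
Corpus Medullare,white_matter
Vermis VI-VII,vermis_VI_VII
Left Crus II,left_crus_II_VIIB
Right Crus II,right_crus_II_VIIB
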