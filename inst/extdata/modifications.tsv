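name	delta	residues
phospho	79.966331	STY
oxidation	15.994915	M
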