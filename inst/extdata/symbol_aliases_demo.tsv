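# alias	canonical (HGNC-style demo map for historic tRNA-synthetase symbols)
GARS	GARS1
AARS	AARS1
HARS	HARS1
KARS	KARS1
MARS	MARS1
YARS	YARS1
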