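molecule_id	smiles
aspirin	CC(=O)Oc1ccccc1C(=O)O
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O
paracetamol	CC(=O)Nc1ccc(O)cc1
benzene	c1ccccc1
cyclohexane	C1CCCCC1
ethanol	CCO
naphthalene	c1ccc2ccccc2c1
toluene	Cc1ccccc1
pyridine	c1ccncc1
nicotine	CN1CCCC1c1cccnc1
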