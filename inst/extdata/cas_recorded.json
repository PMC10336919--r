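{
  "50-00-0": {"smiles": "C=O", "iupac_name": "formaldehyde"},
  "64-17-5": {"smiles": "CCO", "iupac_name": "ethanol"},
  "71-43-2": {"smiles": "c1ccccc1", "iupac_name": "benzene"},
  "50-78-2": {"smiles": "CC(=O)Oc1ccccc1C(=O)O", "iupac_name": "2-acetyloxybenzoic acid"},
  "91-64-5": {"smiles": "O=c1ccc2ccccc2o1", "iupac_name": "chromen-2-one"}
}
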