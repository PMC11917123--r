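[
  {
    "name": "NAD",
    "template_smiles": "NC(=O)c1ccc[n+](c1)C1OC(COP(O)(=O)OP(O)(=O)OCC2OC(n3cnc4c(N)ncnc34)C(O)C2O)C(O)C1O",
    "representative_smiles": "NC(=O)c1ccc[n+](c1)C1OC(COP(O)(=O)OP(O)(=O)OCC2OC(n3cnc4c(N)ncnc34)C(O)C2O)C(O)C1O",
    "threshold": 0.7,
    "ec": ["1.1.1.-", "1.2.1.-", "1.4.1.-", "1.6.-.-", "1.8.1.-"]
  },
  {
    "name": "SAM",
    "template_smiles": "C[S+](CCC(N)C(O)=O)CC1OC(n2cnc3c(N)ncnc23)C(O)C1O",
    "representative_smiles": "C[S+](CCC(N)C(O)=O)CC1OC(n2cnc3c(N)ncnc23)C(O)C1O",
    "threshold": 0.7,
    "ec": ["2.1.1.-", "2.5.1.-"]
  }
]
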