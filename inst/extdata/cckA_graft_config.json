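{
  "_comment": [
    "Worked grafting configuration for the CckA DHp/Rec phosphotransfer",
    "model: the hybrid kinase's DHp-CA structure (PDB 5IDJ) and its Rec",
    "domain structure (PDB 6TNE) are anchored onto the ChpT/CtrA-Rec",
    "phosphotransfer complex (PDB 4QPJ). Anchor residue ranges are the",
    "implementer's reading of the interface helices (C-terminal half of",
    "DHp alpha1' plus N-terminal half of alpha2' on the ChpT side; the",
    "Rec alpha1 helix on the CtrA side) from the helix annotations of the",
    "deposited structures; the primary literature names the helices, not",
    "residue lists, so these extents are a documented choice. Structure",
    "files must be supplied locally (the tool never downloads)."
  ],
  "graft": {
    "template": "4qpj.pdb",
    "components": [
      {
        "file": "5idj.pdb",
        "anchor": {
          "label": "DHp alpha1' C-half + alpha2' N-half",
          "component_chains": ["A"],
          "component_range": [330, 343],
          "template_chains": ["A"],
          "template_range": [30, 43]
        }
      },
      {
        "file": "6tne.pdb",
        "anchor": {
          "label": "Rec alpha1",
          "component_chains": ["A"],
          "component_range": [578, 590],
          "template_chains": ["C"],
          "template_range": [8, 20]
        }
      }
    ]
  },
  "transfer_geometry": {
    "his": {"chain": "A", "resseq": 322},
    "asp": {"chain": "B", "resseq": 623},
    "atom_pair": ["NE2", "CG"]
  }
}
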