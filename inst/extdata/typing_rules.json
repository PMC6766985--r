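{
  "version": "1.0",
  "description": "Channel typing rule constants: metallic element list, halogens, hydrogen-bond 12-10 parameter classes, and the fallback vdW radius for elements missing from vdw_radii.tsv.",
  "default_radius": 1.7,
  "halogens": ["F", "Cl", "Br", "I", "At"],
  "metals": ["Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr",
             "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Rb", "Sr", "Y", "Zr",
             "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Cs",
             "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy",
             "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir",
             "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "Fr", "Ra", "Ac", "Th",
             "Pa", "U", "Np", "Pu"],
  "hbond_classes": {
    "NO": {"elements": ["N", "O"], "epsilon": 5.0, "r_eq": 1.9},
    "S":  {"elements": ["S"],      "epsilon": 1.0, "r_eq": 2.5}
  }
}
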