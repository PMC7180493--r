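[
 {
  "name": "water",
  "formula": "H2O",
  "groups": {},
  "properties": {
   "tb_k": 373.12,
   "tc_k": 647.1,
   "pc_bar": 220.64,
   "vc_cm3_mol": 55.95,
   "omega": 0.3449
  },
  "note": "critical properties supplied directly (experimental values)"
 },
 {
  "name": "ethylene glycol",
  "formula": "C2H6O2",
  "groups": {
   "CH2": 2,
   "OH": 2
  }
 },
 {
  "name": "diethylene glycol",
  "formula": "C4H10O3",
  "groups": {
   "CH2": 4,
   "O": 1,
   "OH": 2
  }
 },
 {
  "name": "triethylene glycol",
  "formula": "C6H14O4",
  "groups": {
   "CH2": 6,
   "O": 2,
   "OH": 2
  }
 },
 {
  "name": "glycerol",
  "formula": "C3H8O3",
  "groups": {
   "CH2": 2,
   "CH": 1,
   "OH": 3
  }
 },
 {
  "name": "1,2-propanediol",
  "formula": "C3H8O2",
  "groups": {
   "CH3": 1,
   "CH2": 1,
   "CH": 1,
   "OH": 2
  }
 },
 {
  "name": "phenol",
  "formula": "C6H6O",
  "groups": {
   "=CH(ring)": 5,
   "=C(ring)": 1,
   "OH(phenol)": 1
  }
 },
 {
  "name": "lactic acid",
  "formula": "C3H6O3",
  "groups": {
   "CH3": 1,
   "CH": 1,
   "OH": 1,
   "COOH": 1
  }
 },
 {
  "name": "levulinic acid",
  "formula": "C5H8O3",
  "groups": {
   "CH3": 1,
   "CH2": 2,
   "C=O": 1,
   "COOH": 1
  }
 },
 {
  "name": "citric acid",
  "formula": "C6H8O7",
  "groups": {
   "CH2": 2,
   "C": 1,
   "OH": 1,
   "COOH": 3
  }
 },
 {
  "name": "oxalic acid",
  "formula": "C2H2O4",
  "groups": {
   "COOH": 2
  }
 },
 {
  "name": "malonic acid",
  "formula": "C3H4O4",
  "groups": {
   "CH2": 1,
   "COOH": 2
  }
 },
 {
  "name": "glutaric acid",
  "formula": "C5H8O4",
  "groups": {
   "CH2": 3,
   "COOH": 2
  }
 },
 {
  "name": "octanoic acid",
  "formula": "C8H16O2",
  "groups": {
   "CH3": 1,
   "CH2": 6,
   "COOH": 1
  }
 },
 {
  "name": "decanoic acid",
  "formula": "C10H20O2",
  "groups": {
   "CH3": 1,
   "CH2": 8,
   "COOH": 1
  }
 },
 {
  "name": "dodecanoic acid",
  "formula": "C12H24O2",
  "groups": {
   "CH3": 1,
   "CH2": 10,
   "COOH": 1
  }
 },
 {
  "name": "urea",
  "formula": "CH4N2O",
  "groups": {
   "NH2": 2,
   "C=O": 1
  }
 },
 {
  "name": "choline chloride",
  "formula": "C5H14ClNO",
  "groups": {
   "CH3": 3,
   "CH2": 2,
   "OH": 1,
   "N+": 1,
   "Cl": 1
  }
 },
 {
  "name": "betaine",
  "formula": "C5H11NO2",
  "groups": {
   "CH3": 3,
   "CH2": 1,
   "N+": 1,
   "COO": 1
  }
 },
 {
  "name": "proline",
  "formula": "C5H9NO2",
  "groups": {
   "CH2(ring)": 3,
   "CH(ring)": 1,
   "NH(ring)": 1,
   "COOH": 1
  }
 },
 {
  "name": "menthol",
  "formula": "C10H20O",
  "groups": {
   "CH3": 3,
   "CH": 1,
   "CH2(ring)": 3,
   "CH(ring)": 3,
   "OH": 1
  }
 },
 {
  "name": "salicylic acid",
  "formula": "C7H6O3",
  "groups": {
   "=CH(ring)": 4,
   "=C(ring)": 2,
   "OH(phenol)": 1,
   "COOH": 1
  }
 },
 {
  "name": "camphor-10-sulfonic acid",
  "formula": "C10H16O4S",
  "groups": {
   "CH3": 2,
   "CH2": 1,
   "C(ring)": 2,
   "CH2(ring)": 3,
   "CH(ring)": 1,
   "C=O": 1,
   "SO3H": 1
  }
 },
 {
  "name": "1-ethyl-3-methylimidazolium chloride",
  "formula": "C6H11ClN2",
  "groups": {
   "CH3": 2,
   "CH2": 1,
   "=CH(ring)": 3,
   "N(ring)": 1,
   "N+(ring)": 1,
   "Cl": 1
  }
 },
 {
  "name": "benzyl trimethyl ammonium chloride",
  "formula": "C10H16ClN",
  "groups": {
   "=CH(ring)": 5,
   "=C(ring)": 1,
   "CH2": 1,
   "CH3": 3,
   "N+": 1,
   "Cl": 1
  }
 },
 {
  "name": "benzyl tripropyl ammonium chloride",
  "formula": "C16H28ClN",
  "groups": {
   "=CH(ring)": 5,
   "=C(ring)": 1,
   "CH2": 7,
   "CH3": 3,
   "N+": 1,
   "Cl": 1
  }
 },
 {
  "name": "benzyl tributyl ammonium chloride",
  "formula": "C19H34ClN",
  "groups": {
   "=CH(ring)": 5,
   "=C(ring)": 1,
   "CH2": 10,
   "CH3": 3,
   "N+": 1,
   "Cl": 1
  }
 },
 {
  "name": "fructose",
  "formula": "C6H12O6",
  "groups": {
   "O(ring)": 1,
   "C(ring)": 1,
   "CH(ring)": 3,
   "CH2": 2,
   "OH": 5
  }
 },
 {
  "name": "glucose",
  "formula": "C6H12O6",
  "groups": {
   "O(ring)": 1,
   "CH(ring)": 5,
   "CH2": 1,
   "OH": 5
  }
 }
]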