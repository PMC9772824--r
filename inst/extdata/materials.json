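{
  "air": {
    "density": 0.001205,
    "comment": "dry air, near sea level",
    "fractions": {"C": 0.000124, "N": 0.755268, "O": 0.231781, "Ar": 0.012827}
  },
  "water": {
    "density": 1.0,
    "fractions": {"H": 0.111898, "O": 0.888102}
  },
  "soft_tissue": {
    "density": 1.0,
    "comment": "ICRU-44 soft tissue composition",
    "fractions": {"H": 0.102, "C": 0.143, "N": 0.034, "O": 0.708,
                  "Na": 0.002, "P": 0.003, "S": 0.003, "Cl": 0.002, "K": 0.003}
  },
  "cortical_bone": {
    "density": 1.92,
    "comment": "ICRU-44 cortical bone",
    "fractions": {"H": 0.034, "C": 0.155, "N": 0.042, "O": 0.435,
                  "Na": 0.001, "Mg": 0.002, "P": 0.103, "S": 0.003, "Ca": 0.225}
  },
  "trabecular_bone": {
    "density": 1.50,
    "comment": "mineral-rich trabecular bone: 0.88 cortical matrix + 0.12 red marrow by mass (bone-equivalent, Ca 19.8%, trace Fe)",
    "fractions": {"H": 0.04252, "C": 0.18608, "N": 0.04104, "O": 0.43524,
                  "Na": 0.001, "Mg": 0.00176, "P": 0.09088, "S": 0.00288,
                  "Cl": 0.00024, "K": 0.00024, "Ca": 0.198, "Fe": 0.00012}
  },
  "bone_marrow": {
    "density": 1.03,
    "comment": "red marrow, ICRU-46-like",
    "fractions": {"H": 0.105, "C": 0.414, "N": 0.034, "O": 0.437,
                  "Na": 0.001, "P": 0.002, "S": 0.002, "Cl": 0.002,
                  "K": 0.002, "Fe": 0.001}
  },
  "copper":    {"density": 8.96,  "fractions": {"Cu": 1.0}},
  "beryllium": {"density": 1.848, "fractions": {"Be": 1.0}},
  "tungsten":  {"density": 19.3,  "fractions": {"W": 1.0}}
}
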