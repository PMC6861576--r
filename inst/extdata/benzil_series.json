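{
  "_schema": "benzilkit molecule summary v1; energies eV, wavelengths nm, dipole Debye, NLO scalars in esu at the scale given by the field suffix (e.g. beta_esu30 = beta / 1e-30 esu)",
  "molecules": [
    {
      "id": "BZL",
      "name": "benzil (1,2-diphenylethane-1,2-dione)",
      "e_homo": -6.596043,
      "e_lumo": -2.62862,
      "ip_vertical": 8.748,
      "ea_vertical": 6.065,
      "dipole_debye": 2.4212,
      "excitations": [
        {
          "lambda_nm": 276.39,
          "f": 0.608,
          "composition": [
            {"donor": "HOMO-3", "acceptor": "LUMO", "weight": 13},
            {"donor": "HOMO-2", "acceptor": "LUMO", "weight": 67},
            {"donor": "HOMO",   "acceptor": "LUMO", "weight": 15}
          ]
        }
      ],
      "nlo": {"mu_debye": 2.4212, "alpha_esu23": 2.275, "beta_esu30": 1.927, "gamma_esu37": -3.807},
      "method_note": "B3LYP/cc-pVDZ; excitations CAM-B3LYP/cc-pVDZ, IEFPCM methanol"
    },
    {
      "id": "DMB",
      "name": "1,2-bis(4-methylphenyl)-1,2-ethanedione",
      "e_homo": -6.423523,
      "e_lumo": -2.46399,
      "ip_vertical": 8.689,
      "ea_vertical": 5.88,
      "dipole_debye": 2.7404,
      "excitations": [
        {
          "lambda_nm": 286.99,
          "f": 0.8355,
          "composition": [
            {"donor": "HOMO-1", "acceptor": "LUMO",   "weight": 78},
            {"donor": "HOMO",   "acceptor": "LUMO+1", "weight": 17}
          ]
        }
      ],
      "nlo": {"mu_debye": 2.7404, "alpha_esu23": 2.757, "beta_esu30": 3.989, "gamma_esu37": -14.386},
      "method_note": "B3LYP/cc-pVDZ; excitations CAM-B3LYP/cc-pVDZ, IEFPCM methanol"
    },
    {
      "id": "DFB",
      "name": "4,4'-difluorobenzil",
      "e_homo": -6.794959,
      "e_lumo": -2.7293,
      "ip_vertical": 8.681,
      "ea_vertical": 5.702,
      "dipole_debye": 1.4873,
      "excitations": [
        {
          "lambda_nm": 271.83,
          "f": 0.7299,
          "composition": [
            {"donor": "HOMO-1", "acceptor": "LUMO",   "weight": 83},
            {"donor": "HOMO",   "acceptor": "LUMO+1", "weight": 13}
          ]
        }
      ],
      "nlo": {"mu_debye": 1.4873, "alpha_esu23": 2.305, "beta_esu30": 3.716, "gamma_esu37": -13.54},
      "method_note": "B3LYP/cc-pVDZ; excitations CAM-B3LYP/cc-pVDZ, IEFPCM methanol"
    },
    {
      "id": "DCB",
      "name": "4,4'-dichlorobenzil",
      "e_homo": -6.82217,
      "e_lumo": -1.75405,
      "ip_vertical": 8.174,
      "ea_vertical": 5.708,
      "dipole_debye": 1.3013,
      "excitations": [
        {
          "lambda_nm": 277.26,
          "f": 0.9581,
          "composition": [
            {"donor": "HOMO-1", "acceptor": "LUMO",   "weight": 81},
            {"donor": "HOMO",   "acceptor": "LUMO+1", "weight": 15}
          ]
        }
      ],
      "nlo": {"mu_debye": 1.3013, "alpha_esu23": 2.745, "beta_esu30": 6.704, "gamma_esu37": -20.195},
      "method_note": "B3LYP/cc-pVDZ; excitations CAM-B3LYP/cc-pVDZ, IEFPCM methanol"
    },
    {
      "id": "DBB",
      "name": "4,4'-dibromobenzil",
      "e_homo": -6.846388,
      "e_lumo": -2.84359,
      "ip_vertical": 8.694,
      "ea_vertical": 5.905,
      "dipole_debye": 1.3607,
      "excitations": [
        {
          "lambda_nm": 279.96,
          "f": 1.036,
          "composition": [
            {"donor": "HOMO-1", "acceptor": "LUMO",   "weight": 79},
            {"donor": "HOMO",   "acceptor": "LUMO+1", "weight": 15}
          ]
        }
      ],
      "nlo": {"mu_debye": 1.3607, "alpha_esu23": 2.966, "beta_esu30": 8.295, "gamma_esu37": -25.09},
      "method_note": "B3LYP/cc-pVDZ; excitations CAM-B3LYP/cc-pVDZ, IEFPCM methanol"
    }
  ]
}
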