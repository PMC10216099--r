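{
  "networks": [
    {
      "name": "DAN",
      "hemisphere": "L",
      "nodes": [
        {
          "label": "G_front_sup_L",
          "index": 1,
          "role": "FEF"
        },
        {
          "label": "G_precentral_L",
          "index": 2,
          "role": "FEF"
        },
        {
          "label": "S_precentral-sup-part_L",
          "index": 3,
          "role": "FEF"
        },
        {
          "label": "G_pariet_inf-Angular_L",
          "index": 7,
          "role": "IPS"
        },
        {
          "label": "G_parietal_sup_L",
          "index": 8,
          "role": "IPS"
        },
        {
          "label": "S_intrapariet_and_P_trans_L",
          "index": 9,
          "role": "IPS"
        }
      ]
    },
    {
      "name": "VAN",
      "hemisphere": "L",
      "nodes": [
        {
          "label": "G_front_inf-Opercular_L",
          "index": 13,
          "role": "VPFC"
        },
        {
          "label": "G_front_inf-Orbital_L",
          "index": 14,
          "role": "VPFC"
        },
        {
          "label": "G_front_inf-Triangul_L",
          "index": 15,
          "role": "VPFC"
        },
        {
          "label": "G_pariet_inf-Supramar_L",
          "index": 19,
          "role": "TPJ"
        },
        {
          "label": "G_temp_sup-Lateral_L",
          "index": 20,
          "role": "TPJ"
        },
        {
          "label": "S_temporal_sup_L",
          "index": 21,
          "role": "TPJ"
        }
      ]
    },
    {
      "name": "DAN",
      "hemisphere": "R",
      "nodes": [
        {
          "label": "G_front_sup_R",
          "index": 4,
          "role": "FEF"
        },
        {
          "label": "G_precentral_R",
          "index": 5,
          "role": "FEF"
        },
        {
          "label": "S_precentral-sup-part_R",
          "index": 6,
          "role": "FEF"
        },
        {
          "label": "G_pariet_inf-Angular_R",
          "index": 10,
          "role": "IPS"
        },
        {
          "label": "G_parietal_sup_R",
          "index": 11,
          "role": "IPS"
        },
        {
          "label": "S_intrapariet_and_P_trans_R",
          "index": 12,
          "role": "IPS"
        }
      ]
    },
    {
      "name": "VAN",
      "hemisphere": "R",
      "nodes": [
        {
          "label": "G_front_inf-Opercular_R",
          "index": 16,
          "role": "VPFC"
        },
        {
          "label": "G_front_inf-Orbital_R",
          "index": 17,
          "role": "VPFC"
        },
        {
          "label": "G_front_inf-Triangul_R",
          "index": 18,
          "role": "VPFC"
        },
        {
          "label": "G_pariet_inf-Supramar_R",
          "index": 22,
          "role": "TPJ"
        },
        {
          "label": "G_temp_sup-Lateral_R",
          "index": 23,
          "role": "TPJ"
        },
        {
          "label": "S_temporal_sup_R",
          "index": 24,
          "role": "TPJ"
        }
      ]
    }
  ]
}
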