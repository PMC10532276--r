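{
  "sepgraph_schema": 1,
  "materials": [
    {
      "id": "CPB_adults",
      "kind": "intermediate",
      "description": "Adult CPB"
    },
    {
      "id": "CPB_eggs",
      "kind": "intermediate",
      "description": "Eggs of CPB"
    },
    {
      "id": "CPB_larvae",
      "kind": "intermediate",
      "description": "Larvae of CPB"
    },
    {
      "id": "CPB_pupae",
      "kind": "intermediate",
      "description": "Pupae of CPB"
    },
    {
      "id": "Chemical_Dosing",
      "kind": "raw",
      "description": "Chemical control strategy against Leptinotarsa decemlineata (CPB)"
    },
    {
      "id": "Control",
      "kind": "product",
      "description": "Overall pest control"
    },
    {
      "id": "E_puttleri_Pop",
      "kind": "intermediate",
      "description": "Edovum puttleri population"
    },
    {
      "id": "E_puttleri_Rep",
      "kind": "raw",
      "description": "Reproductive capacity of E. puttleri"
    },
    {
      "id": "Eclosion",
      "kind": "raw",
      "description": "Eclosion of CPB pupae"
    },
    {
      "id": "Foliage",
      "kind": "intermediate",
      "description": "Foliage of the potato plant"
    },
    {
      "id": "Hatching",
      "kind": "raw",
      "description": "Hatching of CPB eggs"
    },
    {
      "id": "Health_of_E_puttleri",
      "kind": "raw",
      "description": "Overall health of E. puttleri"
    },
    {
      "id": "Health_of_L_decemlineata",
      "kind": "intermediate",
      "description": "Overall health of CPB"
    },
    {
      "id": "Health_of_O_dichrous",
      "kind": "raw",
      "description": "Overall health of Oplomus dichrous"
    },
    {
      "id": "Health_of_Potato",
      "kind": "intermediate",
      "description": "Overall health of the potato plant"
    },
    {
      "id": "Infestation",
      "kind": "raw",
      "description": "Infestation capacity of CPB on the potato plant"
    },
    {
      "id": "L_decemlineata_Est",
      "kind": "raw",
      "description": "Establishment of invading CPB"
    },
    {
      "id": "L_decemlineata_Pop",
      "kind": "intermediate",
      "description": "CPB population"
    },
    {
      "id": "L_decemlineata_Rep",
      "kind": "raw",
      "description": "Reproductive capacity of CPB on the host potato plant"
    },
    {
      "id": "Level_of_Infestation",
      "kind": "product",
      "description": "Observable level of infestation by CPB on the host potato plant"
    },
    {
      "id": "O_dichrous_Pop",
      "kind": "intermediate",
      "description": "O. dichrous population"
    },
    {
      "id": "O_dichrous_Rep",
      "kind": "raw",
      "description": "Reproductive capacity of O. dichrous"
    },
    {
      "id": "Pesticide",
      "kind": "raw",
      "description": "Thiamethoxam"
    },
    {
      "id": "Potato_Rep",
      "kind": "raw",
      "description": "Reproduction of the potato plant"
    },
    {
      "id": "Pupation",
      "kind": "raw",
      "description": "Pupation of CPB larvae"
    },
    {
      "id": "Tuber",
      "kind": "product",
      "description": "Yield of consumable potato tubers"
    },
    {
      "id": "Tuberization",
      "kind": "raw",
      "description": "Formation of tubers by the potato plant"
    },
    {
      "id": "Underground_Bud",
      "kind": "raw",
      "description": "Underground buds of the potato plant"
    },
    {
      "id": "Vegetative_Rep",
      "kind": "raw",
      "description": "Vegetative reproduction of the potato plant via tubers not for human consumption"
    }
  ],
  "units": [
    {
      "id": "cpb_establishment",
      "inputs": {
        "L_decemlineata_Est": 1
      },
      "outputs": {
        "CPB_eggs": 1,
        "Health_of_L_decemlineata": 1
      },
      "capacity": 1
    },
    {
      "id": "cpb_infestation",
      "inputs": {
        "Foliage": 0.8,
        "Health_of_L_decemlineata": 1,
        "Infestation": 1,
        "L_decemlineata_Pop": 1
      },
      "outputs": {
        "Level_of_Infestation": 1
      },
      "capacity": 0.961538
    },
    {
      "id": "cpb_reproduction",
      "inputs": {
        "CPB_adults": 1,
        "L_decemlineata_Rep": 1
      },
      "outputs": {
        "L_decemlineata_Pop": 1
      },
      "capacity": 1
    },
    {
      "id": "e_puttleri_reproduction",
      "inputs": {
        "CPB_eggs": 0.9,
        "E_puttleri_Rep": 1,
        "Health_of_E_puttleri": 1
      },
      "outputs": {
        "Control": 1,
        "E_puttleri_Pop": 1
      },
      "capacity": 1
    },
    {
      "id": "egg_hatching",
      "inputs": {
        "CPB_eggs": 1,
        "Hatching": 1
      },
      "outputs": {
        "CPB_larvae": 1
      },
      "capacity": 1
    },
    {
      "id": "larval_pupation",
      "inputs": {
        "CPB_larvae": 1,
        "Pupation": 1
      },
      "outputs": {
        "CPB_pupae": 1
      },
      "capacity": 1
    },
    {
      "id": "o_dichrous_reproduction",
      "inputs": {
        "CPB_adults": 0.1,
        "CPB_eggs": 0.6,
        "CPB_larvae": 0.27,
        "Health_of_O_dichrous": 1,
        "O_dichrous_Rep": 1
      },
      "outputs": {
        "Control": 1,
        "O_dichrous_Pop": 1
      },
      "capacity": 1
    },
    {
      "id": "pesticide_dosing",
      "inputs": {
        "Chemical_Dosing": 1,
        "Health_of_E_puttleri": 1,
        "Health_of_L_decemlineata": 0.77,
        "Health_of_O_dichrous": 1,
        "Pesticide": 1
      },
      "outputs": {
        "Control": 1
      },
      "capacity": 1
    },
    {
      "id": "potato_reproduction",
      "inputs": {
        "Potato_Rep": 1,
        "Underground_Bud": 1,
        "Vegetative_Rep": 1
      },
      "outputs": {
        "Foliage": 1,
        "Health_of_Potato": 1
      },
      "capacity": 1
    },
    {
      "id": "pupal_eclosion",
      "inputs": {
        "CPB_pupae": 1,
        "Eclosion": 1
      },
      "outputs": {
        "CPB_adults": 1
      },
      "capacity": 1
    },
    {
      "id": "tuberization",
      "inputs": {
        "Foliage": 1,
        "Health_of_Potato": 1,
        "Tuberization": 1
      },
      "outputs": {
        "Tuber": 1
      },
      "capacity": 1
    }
  ],
  "products": [
    "Control",
    "Level_of_Infestation",
    "Tuber"
  ],
  "raws": [
    "Chemical_Dosing",
    "E_puttleri_Rep",
    "Eclosion",
    "Hatching",
    "Health_of_E_puttleri",
    "Health_of_O_dichrous",
    "Infestation",
    "L_decemlineata_Est",
    "L_decemlineata_Rep",
    "O_dichrous_Rep",
    "Pesticide",
    "Potato_Rep",
    "Pupation",
    "Tuberization",
    "Underground_Bud",
    "Vegetative_Rep"
  ]
}
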