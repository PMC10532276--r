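curative_chemical:
  name: curative_chemical
  label: SS1
  description: Chemically controlled system, with two biological control agents eradicated
    as well
  available_raws:
  - Chemical_Dosing
  - Eclosion
  - Hatching
  - Health_of_E_puttleri
  - Health_of_O_dichrous
  - Infestation
  - L_decemlineata_Est
  - L_decemlineata_Rep
  - Pesticide
  - Potato_Rep
  - Pupation
  - Tuberization
  - Underground_Bud
  - Vegetative_Rep
  required_products:
  - Control
  required_flows:
    Control: 1.0
  allow_null: no
biocontrol_parasitoid:
  name: biocontrol_parasitoid
  label: SS2
  description: Biologically controlled system with Edovum puttleri
  available_raws:
  - E_puttleri_Rep
  - Eclosion
  - Hatching
  - Health_of_E_puttleri
  - Infestation
  - L_decemlineata_Est
  - L_decemlineata_Rep
  - Potato_Rep
  - Pupation
  - Tuberization
  - Underground_Bud
  - Vegetative_Rep
  required_products:
  - Control
  required_flows:
    Control: 1.0
  allow_null: no
biocontrol_predator:
  name: biocontrol_predator
  label: SS3
  description: Biologically controlled system with Oplomus dichrous
  available_raws:
  - Eclosion
  - Hatching
  - Health_of_O_dichrous
  - Infestation
  - L_decemlineata_Est
  - L_decemlineata_Rep
  - O_dichrous_Rep
  - Potato_Rep
  - Pupation
  - Tuberization
  - Underground_Bud
  - Vegetative_Rep
  required_products:
  - Control
  required_flows:
    Control: 1.0
  allow_null: no
preventative_chemical:
  name: preventative_chemical
  label: SS4
  description: Insecticide applied prior to CPB establishment, eradicating either
    biological control agent
  available_raws:
  - Chemical_Dosing
  - Health_of_E_puttleri
  - Health_of_O_dichrous
  - L_decemlineata_Est
  - Pesticide
  - Potato_Rep
  - Tuberization
  - Underground_Bud
  - Vegetative_Rep
  required_products:
  - Control
  required_flows:
    Control: 1.0
  allow_null: no
preventative_parasitoid:
  name: preventative_parasitoid
  label: SS5
  description: Biologically controlled system with release of E. puttleri upon detection
    of eggs from invading CPB
  available_raws:
  - E_puttleri_Rep
  - Health_of_E_puttleri
  - L_decemlineata_Est
  - Potato_Rep
  - Tuberization
  - Underground_Bud
  - Vegetative_Rep
  required_products:
  - Control
  required_flows:
    Control: 1.0
  allow_null: no
preventative_predator:
  name: preventative_predator
  label: SS6
  description: Biologically controlled system with release of O. dichrous upon the
    occurrence of immature and mature progeny of invading CPB
  available_raws:
  - Eclosion
  - Hatching
  - Health_of_O_dichrous
  - L_decemlineata_Est
  - O_dichrous_Rep
  - Potato_Rep
  - Pupation
  - Tuberization
  - Underground_Bud
  - Vegetative_Rep
  required_products:
  - Control
  required_flows:
    Control: 1.0
  allow_null: no
uncontrolled:
  name: uncontrolled
  label: SS7
  description: System with uncontrolled CPB infestation
  available_raws:
  - Eclosion
  - Hatching
  - Infestation
  - L_decemlineata_Est
  - L_decemlineata_Rep
  - Potato_Rep
  - Pupation
  - Tuberization
  - Underground_Bud
  - Vegetative_Rep
  required_products: []
  required_flows: []
  allow_null: no
healthy:
  name: healthy
  label: SS8
  description: Completely healthy system, without CPB
  available_raws:
  - Potato_Rep
  - Tuberization
  - Underground_Bud
  - Vegetative_Rep
  required_products: []
  required_flows: []
  allow_null: no
no_potato_chemical:
  name: no_potato_chemical
  label: SS9
  description: System without potato, but with invading CPB and occurring natural
    enemies killed by insecticide
  available_raws:
  - Chemical_Dosing
  - Eclosion
  - Hatching
  - Health_of_E_puttleri
  - Health_of_O_dichrous
  - Infestation
  - L_decemlineata_Est
  - L_decemlineata_Rep
  - Pesticide
  - Pupation
  required_products:
  - Control
  required_flows:
    Control: 1.0
  allow_null: no
'null':
  name: 'null'
  label: SS10
  description: 'Null'
  available_raws: []
  required_products: []
  required_flows: []
  allow_null: yes
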