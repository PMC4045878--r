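metabolites:
- id: glycerol
  name: glycerol
  molar_mass: 92.09
  role: substrate
- id: hpa
  name: 3-hydroxypropionaldehyde
  molar_mass: 74.08
  role: intermediate
- id: pdo
  name: 1,3-propanediol
  molar_mass: 76.09
  role: product
- id: hp
  name: 3-hydroxypropionic acid
  molar_mass: 90.08
  role: product
- id: hp_coa
  name: 3-hydroxypropionyl-CoA
  molar_mass: 839.59
  role: intermediate
- id: hp_phosphate
  name: 3-hydroxypropionyl phosphate
  molar_mass: 170.06
  role: intermediate
- id: nadh
  name: NADH
  molar_mass: 665.44
  role: cofactor
- id: nad
  name: NAD+
  molar_mass: 663.43
  role: cofactor
- id: atp
  name: ATP
  molar_mass: 507.18
  role: cofactor
- id: adp
  name: ADP
  molar_mass: 427.2
  role: cofactor
- id: coa
  name: coenzyme A
  molar_mass: 767.53
  role: cofactor
- id: carbohydrazide
  name: carbohydrazide
  molar_mass: 90.09
  role: scavenger
- id: hpa_complex
  name: 3HPA-carbohydrazide complex
  molar_mass: 146.15
  role: complex
stoichiometry:
  v1:
    glycerol: -1
    hpa: 1
  v2:
    hpa: -1
    pdo: 1
    nadh: -1
    nad: 1
  v3:
    hpa: -1
    hp: 1
    nadh: 1
    nad: -1
    atp: 1
    adp: -1
  v4:
    hpa: 1
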