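schema_version: 1
variant_name: medium_dwell
cycle_length: month
clearance:
  hpv16_18: 0.030370370370370367
  other_hr: 0.035370370370370371
progression_to_precancer:
  hpv16_18: 0.0066666666666666662
  other_hr: 0.0016666666666666666
regression_from_precancer:
  hpv16_18: 0.0075555555555555558
  other_hr: 0.0075555555555555558
progression_to_cancer: 0.0035555555555555557
symptomatic_detection_rate: 0.015873015873015876
occult_fraction: 0
cyto_sens_precancer: 0.55000000000000004
cyto_sens_cancer: 0.80000000000000004
cyto_spec: 0.96999999999999997
hpv_sens: 0.90000000000000002
hpv_spec: 0.93999999999999995
colposcopy_sens: 0.94999999999999996
colposcopy_compliance: 0.79000000000000004
treatment_compliance: 0.72999999999999998
vaccine_efficacy_16_18: 0.94999999999999996
hpv_incidence:
  age: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70, 71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84]
  hpv16_18: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2.9141491639191453e-05, 9.5436141582283711e-05, 0.00017580713415417008, 0.00025589103527560086, 0.0003273529062767142, 0.00038594000372860828, 0.00043008518180240242, 0.00045991701522907653, 0.00047656882098097241, 0.00048170561690770062, 0.00047720851501620998, 0.00046497158107372208, 0.00044677794466504772, 0.00042423080027498527, 0.000398721584603587, 0.00037142257576498175, 0.00034329484223843634, 0.00031510518507690821, 0.00028744770455902042, 0.00026076706440348365, 0.00023538156155624115, 0.00021150484264478113, 0.00018926561901435696, 0.00016872508069100081, 0.00014989194051354853, 0.00013273518647007504, 0.00011719470772365791, 0.00010319000612907279, 9.0627223509052451e-05, 7.9404715169607319e-05, 6.9417388934504221e-05, 6.0560011182009457e-05, 5.2729660291432956e-05, 4.5827485784043559e-05, 3.9759909719601729e-05, 3.4439386474976764e-05, 2.9784818382972001e-05, 2.5721708077073347e-05, 2.2182113821678454e-05, 1.9104461542757984e-05, 1.6433256576720458e-05, 1.4118729153762462e-05, 1.2116440138600249e-05, 1.0386867377179929e-05, 8.894987961480007e-06, 7.6098676577548593e-06, 6.5042654944568118e-06, 5.5542589396497214e-06, 4.7388930960431047e-06, 4.0398558030814472e-06, 3.4411793730162565e-06, 2.9289688282554501e-06, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
  other_hr: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 8.7424474917574351e-05, 0.00028630842474685112, 0.00052742140246251029, 0.00076767310582680258, 0.00098205871883014261, 0.0011578200111858248, 0.0012902555454072074, 0.0013797510456872296, 0.0014297064629429173, 0.001445116850723102, 0.0014316255450486299, 0.0013949147432211662, 0.0013403338339951431, 0.0012726924008249559, 0.001196164753810761, 0.0011142677272949451, 0.001029884526715309, 0.00094531555523072464, 0.00086234311367706126, 0.0007823011932104509, 0.00070614468466872343, 0.00063451452793434335, 0.00056779685704307081, 0.00050617524207300247, 0.00044967582154064559, 0.00039820555941022512, 0.00035158412317097369, 0.00030957001838721835, 0.00027188167052715737, 0.00023821414550882194, 0.00020825216680351265, 0.00018168003354602838, 0.00015818898087429885, 0.00013748245735213069, 0.00011927972915880519, 0.00010331815942493029, 8.9354455148916005e-05, 7.7165124231220035e-05, 6.6546341465035361e-05, 5.7313384628273951e-05, 4.9299769730161374e-05, 4.2356187461287384e-05, 3.6349320415800745e-05, 3.1160602131539785e-05, 2.6684963884440021e-05, 2.2829602973264578e-05, 1.9512796483370434e-05, 1.6662776818949163e-05, 1.4216679288129314e-05, 1.2119567409244343e-05, 1.0323538119048769e-05, 8.7869064847663496e-06, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
metadata:
  dwell_target_years: 15
  stylized: true
  seed: 1
  acquisition_amplitude: 0.0019268224676308025
  calibrated: true
  target_lifetime_risk: 1
  achieved_lifetime_risk: 1.0000001196225401
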