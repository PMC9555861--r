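schema_version: 1
variant_name: long_dwell
cycle_length: month
clearance:
  hpv16_18: 0.022777777777777779
  other_hr: 0.026527777777777775
progression_to_precancer:
  hpv16_18: 0.0049999999999999992
  other_hr: 0.0012499999999999998
regression_from_precancer:
  hpv16_18: 0.0056666666666666671
  other_hr: 0.0056666666666666671
progression_to_cancer: 0.0026666666666666666
symptomatic_detection_rate: 0.011904761904761904
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
  hpv16_18: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3.1036092733709172e-05, 0.00010164081430587114, 0.00018723703599023668, 0.00027252750129844568, 0.00034863538495708918, 0.00041103145623679158, 0.00045804668309641411, 0.00048981799940754146, 0.00050755240346270366, 0.00051302316236241858, 0.00050823368648159116, 0.00049520118212946094, 0.00047582470704252296, 0.00045181168558039561, 0.00042464401712525847, 0.00039557019412596312, 0.0003656137678411504, 0.00033559139202631619, 0.0003061357917172533, 0.00027772053994104263, 0.00025068462735929682, 0.00022525559059316988, 0.00020157050901034219, 0.00017969455083712918, 0.00015963699536772184, 0.00014136481437934136, 0.00012481398899704047, 0.00010989878757979662, 9.6519249867182841e-05, 8.456712285047852e-05, 7.3930481904563419e-05, 6.4497251762897709e-05, 5.6157819472116132e-05, 4.88069079014988e-05, 4.234485524693964e-05, 3.6678424205710445e-05, 3.1721244637573833e-05, 2.7393975814053215e-05, 2.3624258844507304e-05, 2.034651648617766e-05, 1.7501646152732185e-05, 1.503664234911665e-05, 1.2904176779966195e-05, 1.106215780311509e-05, 9.473285535818228e-06, 8.104614590136574e-06, 6.9271329535905409e-06, 5.9153627979073745e-06, 5.0469868668674877e-06, 4.3025024555238484e-06, 3.6649037549823572e-06, 3.1193924214101008e-06, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
  other_hr: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 9.3108278201127517e-05, 0.0003049224429176134, 0.00056171110797071007, 0.00081758250389533699, 0.0010459061548712676, 0.0012330943687103748, 0.0013741400492892422, 0.0014694539982226243, 0.001522657210388111, 0.0015390694870872556, 0.0015247010594447736, 0.0014856035463883827, 0.0014274741211275689, 0.0013554350567411867, 0.0012739320513757754, 0.0011867105823778893, 0.0010968413035234513, 0.0010067741760789485, 0.00091840737515175991, 0.00083316161982312795, 0.00075205388207789047, 0.00067576677177950961, 0.00060471152703102653, 0.00053908365251138758, 0.00047891098610316552, 0.00042409444313802407, 0.00037444196699112139, 0.00032969636273938989, 0.00028955774960154855, 0.00025370136855143557, 0.00022179144571369026, 0.00019349175528869314, 0.0001684734584163484, 0.00014642072370449639, 0.00012703456574081893, 0.00011003527261713134, 9.5163733912721499e-05, 8.2181927442159642e-05, 7.0872776533521914e-05, 6.1039549458532976e-05, 5.2504938458196554e-05, 4.5109927047349949e-05, 3.8712530339898588e-05, 3.3186473409345271e-05, 2.8419856607454684e-05, 2.4313843770409722e-05, 2.0781398860771624e-05, 1.7746088393722123e-05, 1.5140960600602464e-05, 1.2907507366571545e-05, 1.0994711264947071e-05, 9.3581772642303033e-06, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
metadata:
  dwell_target_years: 20
  stylized: true
  seed: 1
  acquisition_amplitude: 0.0020520926494496743
  calibrated: true
  target_lifetime_risk: 1
  achieved_lifetime_risk: 0.99999977994611366
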