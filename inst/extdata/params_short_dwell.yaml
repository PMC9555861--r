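schema_version: 1
variant_name: short_dwell
cycle_length: month
clearance:
  hpv16_18: 0.045555555555555557
  other_hr: 0.05305555555555555
progression_to_precancer:
  hpv16_18: 0.0099999999999999985
  other_hr: 0.0024999999999999996
regression_from_precancer:
  hpv16_18: 0.011333333333333334
  other_hr: 0.011333333333333334
progression_to_cancer: 0.0053333333333333332
symptomatic_detection_rate: 0.023809523809523808
occult_fraction: 0.10000000000000001
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
  hpv16_18: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2.7751079584058533e-05, 9.0882649146332989e-05, 0.00016741894449892323, 0.00024368184623844316, 0.00031173409606598989, 0.00036752585937435624, 0.00040956476270663218, 0.00043797324617796693, 0.00045383055342773296, 0.00045872226021936434, 0.00045443972609127126, 0.00044278664628645618, 0.00042546107290291902, 0.00040398970808368001, 0.00037969759967040152, 0.00035370109351259013, 0.00032691540315470249, 0.00030007074369036639, 0.00027373286941648282, 0.00024832522805490729, 0.00022415092982345556, 0.00020141342774490699, 0.00018023529203048204, 0.00016067479317996141, 0.00014274022832126603, 0.00012640206510163747, 0.00011160306071964498, 9.8266557794048469e-05, 8.6303176351468168e-05, 7.5616121415616455e-05, 6.6105315015797185e-05, 5.7670544484525516e-05, 5.0213798844118718e-05, 4.3640944014682894e-05, 3.7862866889069918e-05, 3.2796198860592939e-05, 2.8363711630703576e-05, 2.4494462284998828e-05, 2.1123750754754538e-05, 1.8192940816064978e-05, 1.5649185591876444e-05, 1.344508995019654e-05, 1.1538335055902652e-05, 9.8912844538653533e-06, 8.4705862649219954e-06, 7.2467822035058868e-06, 6.193931031648622e-06, 5.2892516200987646e-06, 4.5127888811214798e-06, 3.8471043722641957e-06, 3.2769922633323513e-06, 2.7892205402015205e-06, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
  other_hr: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 8.3253238752175593e-05, 0.00027264794743899899, 0.00050225683349676973, 0.00073104553871532944, 0.00093520228819796961, 0.0011025775781230687, 0.0012286942881198967, 0.0013139197385339009, 0.0013614916602831988, 0.0013761667806580931, 0.0013633191782738137, 0.0013283599388593686, 0.0012763832187087571, 0.00121196912425104, 0.0011390927990112046, 0.0010611032805377704, 0.00098074620946410752, 0.00090021223107109916, 0.0008211986082494484, 0.00074497568416472188, 0.00067245278947036672, 0.00060424028323472097, 0.00054070587609144618, 0.00048202437953988423, 0.00042822068496379813, 0.00037920619530491242, 0.00033480918215893495, 0.00029479967338214539, 0.00025890952905440449, 0.00022684836424684935, 0.00019831594504739154, 0.00017301163345357655, 0.00015064139653235615, 0.00013092283204404868, 0.00011358860066720976, 9.8388596581778818e-05, 8.5091134892110722e-05, 7.3483386854996484e-05, 6.337125226426361e-05, 5.4578822448194935e-05, 4.6947556775629327e-05, 4.033526985058962e-05, 3.4615005167707956e-05, 2.967385336159606e-05, 2.5411758794765984e-05, 2.174034661051766e-05, 1.8581793094945868e-05, 1.5867754860296296e-05, 1.353836664336444e-05, 1.1541313116792587e-05, 9.8309767899970543e-06, 8.3676616206045618e-06, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
metadata:
  dwell_target_years: 10
  stylized: true
  seed: 1
  acquisition_amplitude: 0.0018348890408774574
  calibrated: true
  target_lifetime_risk: 1
  achieved_lifetime_risk: 1.0000000755457912
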