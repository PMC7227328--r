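species,n_samples,c_min,c_max,c_mean,c_se,n_min,n_max,n_mean,n_se,cn_mean,cn_se,dbh_min,dbh_max
Terminalia macroptera,19,46.267,51.241,49.474,0.266,0.108,0.303,0.192,0.013,281.81,18.33,9.3,40.7
Terminalia avicennioides,3,47.971,49.759,48.70,0.53,0.155,0.181,0.168,0.007,289.96,13.67,16.6,24.2
Acacia seyal,14,43.928,53.071,46.50,0.684,0.13,0.583,0.290,0.037,194.24,21.72,7.6,34.4
Acacia gourmaensis,2,47.55,48.09,47.824,0.269,0.297,0.349,0.323,0.025,148.95,11.15,13.4,19
Combretum glutinosum,11,41.737,45.959,44.72,0.438,0.14,0.358,0.241,0.020,201.36,19.15,8,32
Pterocarpus erinaceus,21,46.779,51.645,49.438,0.278,0.164,0.427,0.242,0.014,216.28,10.63,6.9,44.7
Anogeisus leiocarpus,16,44.037,46.003,44.917,0.167,0.08,0.273,0.128,0.012,386.52,28.28,6.9,32.4
Mitragyna inermis,18,44.978,47.74,46.724,0.174,0.177,0.354,0.243,0.011,199.40,9.23,7,34.5
Lannea microcrapa,20,42.091,45.938,44.282,0.209,0.148,0.405,0.273,0.015,173.47,11.14,7,50.3
Lannea acida,6,43.408,45.164,44.526,0.248,0.14,0.386,0.265,0.035,186.92,30.61,10.8,36
Ficus sp,21,43.931,46.38,45.153,0.139,0.16,0.427,0.294,0.015,163.14,9.83,8.6,52.7
Crosopteryx febrifuga,18,47.662,52.229,49.172,0.217,0.118,0.306,0.182,0.014,295.68,20.50,5.6,30.6
Entada Africana,15,45.852,48.377,47.098,0.191,0.242,0.475,0.357,0.016,135.97,6.75,8.4,27.6
Parkia biglobosa,23,44.02,47.636,46.516,0.214,0.127,0.396,0.201,0.013,247.85,12.35,8.6,62.4
Vitelaria paradoxa,22,45.972,50.032,47.942,0.228,0.13,0.337,0.228,0.010,220.11,11.37,8,60
Azadirachta indica,16,47.253,52.999,49.005,0.413,0.104,0.302,0.177,0.014,302.38,22.53,8.8,50.5
Anacardium occidentale,25,44.928,47.693,46.446,0.138,0.103,0.32,0.161,0.011,375.79,17.58,9.2,57.9
Eucalyptus grandis,7,47.018,49.031,47.744,0.350,0.125,0.191,0.157,0.011,310.57,21.94,5.7,29.2
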