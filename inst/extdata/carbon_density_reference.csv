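lulc,category,element,min_density,max_density,mean_density,se_density,total_stock,se_total
Riparian forest and woodland,Forest land,C,35.46,57.27,44.81,2.38,15291.86,813.16
Savannah Woodland,Forest land,C,12.50,31.90,21.25,1.16,116401.70,6397.49
Shrub Savannah,Forest land,C,2.76,12.22,6.57,0.35,28147.43,1510.82
Savannah grassland,Grassland,C,0.03,2.98,1.67,0.15,161.55,15.23
Cropland and Fallow,Cropland,C,0.03,4.33,1.52,0.14,12272.24,2326.92
Settlements,Settlements,C,0.41,4.57,2.30,0.48,1125.66,1187.20
Cashew plantation,Agroforestry,C,4.99,98.08,21.39,6.68,442.91,138.47
Eucalyptus grandis,Plantation,C,3.67,331.91,97.83,27.55,1346.27,379.15
Tectona grandis,Plantation,C,16.52,108.70,82.62,33.09,74.36,29.78
Azadirachta indica plantation,Plantation,C,31.58,117.87,88.02,28.23,63.37,0.32
Gmelina arborea,Plantation,C,4.88,16.16,11.82,3.50,20.34,6.02
Riparian forest and woodland,Forest land,N,0.170,0.285,0.212,0.014,72.41,0.014
Savannah Woodland,Forest land,N,0.045,0.160,0.096,0.005,530.79,0.005
Shrub Savannah,Forest land,N,0.008,0.064,0.032,0.001,137.16,0.001
Savannah grassland,Grassland,N,0.0001,0.0178,0.0085,0.0068,0.825,0.0006
Cropland and Fallow,Cropland,N,0.00018,0.0252,0.0077,0.0067,62.57,0.0006
Settlements,Settlements,N,0.0017,0.0201,0.0106,0.0021,5.20,0.002
Cashew plantation,Agroforestry,N,0.017,0.340,0.0741,0.022,1.53,0.022
Eucalyptus grandis,Plantation,N,0.012,1.091,0.321,0.088,4.42,0.088
Tectona grandis,Plantation,N,0.058,0.418,0.291,0.115,0.26,0.115
Azadirachta indica plantation,Plantation,N,0.114,0.425,0.317,0.101,0.23,0.101
Gmelina arborea,Plantation,N,0.024,0.079,0.058,0.017,0.10,0.017
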