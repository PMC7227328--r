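lulc,category,area_ha,percent_basin,area_sampled_ha,n_plots,plot_width_m,plot_length_m
Riparian forest and woodland,Forest land,320.40,1.66,0.81,9,30,30
Savannah Woodland,Forest land,5447.79,28.29,2.43,27,30,30
Shrub Savannah,Forest land,4241.88,22.03,5.04,56,30,30
Savannah grassland,Grassland,96.48,0.50,3.06,34,30,30
Cropland and Fallow,Cropland,8031.15,41.70,7.20,80,30,30
Settlements,Settlements,486.72,2.53,8.00,8,100,100
Cashew plantation,Agroforestry,20.70,0.11,0.26,13,10,20
Plantation,Plantation,16.74,0.09,0.46,23,10,20
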