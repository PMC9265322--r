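from,paddy_field,dry_land,woodland,grassland,water_area,bottomland,construction_land,unutilized_land
paddy_field,NA,238.08,4.21,3.18,102.43,2.02,421.29,NA
dry_land,2442.75,NA,174.15,214.17,236.06,12.95,4406.21,NA
woodland,58.03,405.23,NA,73.56,11.92,0.13,202.29,NA
grassland,NA,381.09,141.9,NA,14.54,3.55,183.59,NA
water_area,53.02,438.17,4.79,1.1,NA,107.09,97.2,1.06
bottomland,NA,3.22,NA,NA,0.39,NA,1.72,NA
construction_land,433.34,1076.13,16.48,13.64,40.38,0.34,NA,NA
unutilized_land,4.5,4.26,2.49,0.05,0.44,0.23,0.9,NA
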