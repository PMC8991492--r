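category,who_category,weight_raw,is_beverage,is_cheese,is_added_fat,is_water,energy_med,sugars_med,totfat_med,satratio,sodium_med,fibre_med,protein_med,fv_mean,marker_p
confectionery,confectionery,0.06,FALSE,FALSE,FALSE,FALSE,2000,50,25,0.60,100,2,5,0,0.85
sweet_bakery,sweet_bakery,0.07,FALSE,FALSE,FALSE,FALSE,1800,30,18,0.50,300,2.5,6,0,0.80
savoury_snacks,savoury_snacks,0.05,FALSE,FALSE,FALSE,FALSE,2100,3,28,0.40,700,4,7,0,0.75
breakfast_cereals,breakfast_cereals,0.04,FALSE,FALSE,FALSE,FALSE,1600,18,5,0.35,350,7,9,5,0.60
yoghurts,yoghurts,0.07,FALSE,FALSE,FALSE,FALSE,400,11,3,0.65,60,0.3,4,5,0.50
cheese,cheese,0.05,FALSE,TRUE,FALSE,FALSE,1400,1.5,27,0.66,700,0.1,22,0,0.15
ready_meals,ready_meals,0.09,FALSE,FALSE,FALSE,FALSE,600,3.5,6,0.40,450,2,7,15,0.65
butter_oils,butter_oils,0.02,FALSE,FALSE,TRUE,FALSE,3100,0.5,82,0.45,150,0,0.5,0,0.25
bread,bread,0.07,FALSE,FALSE,FALSE,FALSE,1100,4,3,0.30,450,4,9,0,0.45
pasta_rice_grains,pasta_rice_grains,0.05,FALSE,FALSE,FALSE,FALSE,1500,2,2,0.25,10,3,11,0,0.20
fresh_meat_fish,fresh_meat_fish,0.06,FALSE,FALSE,FALSE,FALSE,700,0.3,8,0.35,80,0,20,0,0.05
processed_meat,processed_meat,0.08,FALSE,FALSE,FALSE,FALSE,1000,1,15,0.38,900,0.3,16,0,0.50
fresh_fruit_veg,fresh_fruit_veg,0.08,FALSE,FALSE,FALSE,FALSE,180,5,0.3,0.20,10,2.5,1.2,100,0.02
processed_fruit_veg,processed_fruit_veg,0.06,FALSE,FALSE,FALSE,FALSE,300,7,1,0.30,250,2.5,1.5,70,0.35
sauces,sauces,0.05,FALSE,FALSE,FALSE,FALSE,800,8,15,0.15,900,1,1.5,20,0.70
soft_drinks,soft_drinks,0.05,TRUE,FALSE,FALSE,FALSE,160,9,0,0.00,10,0,0,0,0.70
juices,juices,0.04,TRUE,FALSE,FALSE,FALSE,180,9.5,0.1,0.20,5,0.3,0.5,95,0.15
milk_drinks,milk_drinks,0.04,TRUE,FALSE,FALSE,FALSE,350,10,1.8,0.65,50,0.2,3.3,0,0.55
energy_drinks,energy_drinks,0.01,TRUE,FALSE,FALSE,FALSE,200,11,0,0.00,90,0,0,0,0.90
edible_ices,edible_ices,0.02,FALSE,FALSE,FALSE,FALSE,900,22,10,0.70,70,0.7,3.5,2,0.80
water,soft_drinks,0.015,TRUE,FALSE,FALSE,TRUE,0,0,0,0.00,0,0,0,0,0.01
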