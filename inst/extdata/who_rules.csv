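who_category,label,always_prohibited,energy_kj_max,total_fat_g_max,saturated_fat_g_max,total_sugars_g_max,added_sugars_g_max,salt_g_max,no_sweeteners
confectionery,"Chocolate and sugar confectionery, energy bars, sweet toppings and desserts",TRUE,NA,NA,NA,NA,NA,NA,FALSE
sweet_bakery,"Cakes, sweet biscuits and pastries, other sweet bakery wares",TRUE,NA,NA,NA,NA,NA,NA,FALSE
savoury_snacks,"Savoury snacks",FALSE,NA,NA,NA,10,NA,0.1,TRUE
juices,"Juices (fruit and vegetable)",TRUE,NA,NA,NA,NA,NA,NA,FALSE
milk_drinks,"Milk drinks",FALSE,NA,2.5,NA,NA,NA,NA,TRUE
energy_drinks,"Energy drinks",TRUE,NA,NA,NA,NA,NA,NA,FALSE
soft_drinks,"Other beverages (soft drinks, waters)",FALSE,NA,NA,NA,0,NA,NA,TRUE
edible_ices,"Edible ices",TRUE,NA,NA,NA,NA,NA,NA,FALSE
breakfast_cereals,"Breakfast cereals",FALSE,NA,10,NA,15,NA,1.6,FALSE
yoghurts,"Yoghurts, sour milk, cream and similar",FALSE,NA,2.5,NA,10,NA,0.2,FALSE
cheese,"Cheese",FALSE,NA,20,NA,NA,NA,1.3,FALSE
ready_meals,"Ready-made and convenience foods and composite dishes",FALSE,941,10,NA,10,NA,1.0,FALSE
butter_oils,"Butter and other fats and oils",FALSE,NA,NA,20,NA,NA,1.3,FALSE
bread,"Bread, bread products and crisp breads",FALSE,NA,10,NA,10,NA,1.2,FALSE
pasta_rice_grains,"Fresh or dried pasta, rice and grains",FALSE,NA,10,NA,10,NA,1.2,FALSE
fresh_meat_fish,"Fresh and frozen meat, poultry, fish and similar",FALSE,NA,10,NA,NA,NA,NA,FALSE
processed_meat,"Processed meat, poultry, fish and similar",FALSE,NA,20,NA,NA,NA,1.7,FALSE
fresh_fruit_veg,"Fresh and frozen fruit, vegetables and legumes",FALSE,NA,NA,NA,NA,NA,1.0,FALSE
processed_fruit_veg,"Processed fruit, vegetables and legumes",FALSE,NA,5,NA,10,NA,1.0,FALSE
sauces,"Sauces, dips and dressings",FALSE,NA,10,NA,10,NA,1.0,FALSE
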