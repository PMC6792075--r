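name,total_fruit,whole_fruit,total_veg,greens_beans,whole_grains,refined_grains,dairy,total_protein,seafood_plant_protein,mufa,pufa,sfa,added_sugar,solid_fat_kcal,alcohol,groups_known
Sandwich 0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,FALSE
Sandwich 1,0,0,0.2,0.1,2.0,0,1.0,2.5,0,7.6,4.1,10.3,0.5,170,0,TRUE
Sandwich 2,0,0,0.2,0.1,0,2.0,1.0,2.5,0,7.6,4.1,10.3,0.5,170,0,TRUE
Sandwich 3,0,0,0.2,0.1,2.0,0,1.0,2.5,0,4.8,2.6,8.6,0.5,130,0,TRUE
Sandwich 4,0,0,0.2,0.1,0,2.0,1.0,2.5,0,4.8,2.6,8.6,0.5,130,0,TRUE
Sandwich 5,0,0,0.2,0,1.0,0,0.33,1.5,0,4.0,2.2,3.8,0.2,60,0,TRUE
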