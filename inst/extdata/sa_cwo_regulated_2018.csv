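level,category,n,regulated_overall,regulated_sugar,regulated_sodium,regulated_sat_fat,regulated_energy,regulated_energy_only
category,breakfast cereals,110,97,74,16,31,94,11
category,cereals & cereal products,254,106,1,71,34,47,10
category,confectionery & dessert,1119,1057,997,83,600,912,12
category,dairy,791,515,262,246,56,74,3
category,fruits & vegetables (all),706,293,129,163,13,29,8
category,legumes,100,28,0,28,0,3,0
category,mixed dishes,299,211,14,177,113,36,3
category,protein,602,412,6,390,88,88,3
category,snack foods,699,564,95,388,394,552,35
category,soups & sauces,610,480,206,416,106,244,12
food total,food total,5290,3763,1784,1978,1435,2079,97
category,dairy drinks,306,139,135,4,0,39,1
category,other beverages,478,246,243,1,0,3,2
category,sodas,288,190,190,0,0,2,0
category,100% fruit juice,385,6,3,3,0,0,0
beverage total,beverage total,1457,581,571,8,0,44,3
food & beverage total,food & beverage total,6747,4344,2355,1986,1435,2123,100
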