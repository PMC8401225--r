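level,category,n,mean_energy_kJ,mean_total_sugar_g,mean_free_sugar_g,mean_total_fat_g,mean_sat_fat_g,mean_trans_fat_g,mean_sodium_mg,nss_count,nss_pct
category,breakfast cereals,110,1588.2,17.2,16.3,8.9,2.9,0.03,210.6,0,0
category,cereals & cereal products,254,989.9,3.1,3.2,6.1,2.4,0.11,338.5,8,3.2
category,confectionery & dessert,1119,1559.8,38.4,35.1,14.0,7.7,0.12,142.5,143,12.8
category,dairy,791,766.5,6.4,3.5,12.6,8.8,0.33,322.1,70,8.9
category,fruits & vegetables,196,677.4,29.8,15.2,2.1,1.2,0.02,41.9,0,0
category,vegetables,510,315.9,3.3,3.3,3.6,0.7,0.03,392.6,5,1.0
category,legumes,100,342.7,2.1,2.1,0.8,0.2,0.03,290.3,0,0
category,mixed dishes,299,813.0,3.3,3.2,9.3,4.0,0.17,429.2,10,3.3
category,protein,602,787.4,1.4,1.4,9.9,3.5,0.13,826.0,18,3.0
category,snack foods,699,2059.4,6.8,6.1,27.9,7.7,0.06,476.8,58,8.3
category,soups & sauces,610,676.1,9.7,9.6,11.2,2.2,0.07,746.3,35,5.9
food total,food total,5290,1072.8,13.4,11.6,12.4,5.1,0.12,411.2,347,6.6
category,dairy drinks,306,255.1,6.0,4.9,1.8,1.1,0.07,43.3,58,19.0
category,other beverages,478,116.7,5.8,4.0,0.1,0.08,0.004,13.4,213,44.6
category,sodas,288,125.1,6.9,6.9,0.04,0.02,0.01,18.6,160,55.6
category,100% fruit juice,385,190.0,10.4,6.0,0.05,0.02,0.0,9.5,1,0.3
beverage total,beverage total,1457,160.7,7.2,5.1,0.45,0.3,0.01,19.7,432,29.6
food & beverage total,food & beverage total,6747,875.7,12.1,10.7,9.8,4.1,0.09,326.6,779,11.5
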