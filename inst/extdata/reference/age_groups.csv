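age_group,label,n_activities,population,tu_total,tu_physician,tu_nurse,tu_hp,tr_total,tr_physician,tr_nurse,tr_hp
newborns,Newborns,10,5601,55.50,24.00,27.00,5.00,90.00,41.00,43.50,10.00
children_under_5,Children under 5 years,10,41094,61.50,13.50,33.50,15.50,94.00,20.00,46.00,22.50
children_5_9,Children from 5 to 9 years,10,24266,71.00,30.00,20.00,14.00,94.50,40.00,30.00,22.50
teens_10_19,Teens from 10 to 19 years,10,50508,97.50,60.00,17.50,27.50,131.00,77.50,25.00,35.00
women_20_59,Women from 20 to 59 years,11,76839,97.50,40.00,25.00,35.50,165.40,57.50,37.50,76.50
men_20_59,Men from 20 to 59 years,11,39459,83.50,37.50,32.50,25.00,152.50,51.50,30.00,62.50
over_60,Women and men over 60 years,10,16591,100.00,52.50,39.50,15.00,162.50,70.00,72.50,20.00
pregnant_first_visit,Pregnant women - first visit,10,7610,61.50,46.00,10.00,5.00,85.50,67.00,10.00,9.00
pregnant_subsequent,Pregnant women - subsequent visits,7,5076,46.50,36.50,10.00,0.00,58.50,47.00,10.00,0.00
postnatal,Postnatal care,10,1483,58.50,27.50,35.00,0.00,91.50,37.00,50.00,0.00
all_groups,All groups,99,268527,73.00,40.00,25.00,22.00,105.00,51.00,35.00,30.00
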