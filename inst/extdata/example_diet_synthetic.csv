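dataset_id,study_id,species,lat,lon,sample_type,n_samples,category,F,V,npp,gsl,co_occurrence
ds001,st001,species1,67.7804109104909,-21.804646952077746,scat,231,herptiles,0,NA,1.5690343977379906,9,none
ds001,st001,species1,67.7804109104909,-21.804646952077746,scat,231,small_mammals,0,NA,1.5690343977379906,9,none
ds001,st001,species1,67.7804109104909,-21.804646952077746,scat,231,ungulates,0,NA,1.5690343977379906,9,none
ds001,st001,species1,67.7804109104909,-21.804646952077746,scat,231,hard_mast,0.041872207046788255,NA,1.5690343977379906,9,none
ds001,st001,species1,67.7804109104909,-21.804646952077746,scat,231,graminoids,0.006704643558371069,NA,1.5690343977379906,9,none
ds001,st001,species1,67.7804109104909,-21.804646952077746,scat,231,forbs,0.5684876418137119,NA,1.5690343977379906,9,none
ds001,st001,species1,67.7804109104909,-21.804646952077746,scat,231,browse_foliage,0.3605299883719797,NA,1.5690343977379906,9,none
ds001,st001,species1,67.7804109104909,-21.804646952077746,scat,231,roots_tubers,0.022405519209149162,NA,1.5690343977379906,9,none
ds002,st002,species2,60.450704533141106,144.67478021979332,scat,96,ungulates,0.049459964410147175,0.05927694788614362,0.49093176845362774,6,none
ds002,st002,species2,60.450704533141106,144.67478021979332,scat,96,herptiles,0.0014599365624450042,0.0012438611025045543,0.49093176845362774,6,none
ds002,st002,species2,60.450704533141106,144.67478021979332,scat,96,other_insects,0.02214792193917663,0.016767076405809968,0.49093176845362774,6,none
ds002,st002,species2,60.450704533141106,144.67478021979332,scat,96,browse_foliage,0.19811644838638562,0.25511838839572126,0.49093176845362774,6,none
ds002,st002,species2,60.450704533141106,144.67478021979332,scat,96,seeds,0.08450278133051894,0.10033781499135593,0.49093176845362774,6,none
ds002,st002,species2,60.450704533141106,144.67478021979332,scat,96,bamboo,0.17652925349386484,0.18896498684641846,0.49093176845362774,6,none
ds002,st002,species2,60.450704533141106,144.67478021979332,scat,96,other_debris,0.08897163494357872,0.08441390512765694,0.49093176845362774,6,none
ds002,st002,species2,60.450704533141106,144.67478021979332,scat,96,fungi,0.378812058933883,0.2938770192443892,0.49093176845362774,6,none
ds003,st003,species1,-18.248078965116292,119.49392261914909,scat,35,carrion,0,NA,0.28275532045662677,8,subordinate
ds003,st003,species1,-18.248078965116292,119.49392261914909,scat,35,other_insects,0,NA,0.28275532045662677,8,subordinate
ds003,st003,species1,-18.248078965116292,119.49392261914909,scat,35,fish,0,NA,0.28275532045662677,8,subordinate
ds003,st003,species1,-18.248078965116292,119.49392261914909,scat,35,roots_tubers,0.03890640417334971,NA,0.28275532045662677,8,subordinate
ds003,st003,species1,-18.248078965116292,119.49392261914909,scat,35,graminoids,0.16975263006907435,NA,0.28275532045662677,8,subordinate
ds003,st003,species1,-18.248078965116292,119.49392261914909,scat,35,fleshy_fruits,0.12736328650161075,NA,0.28275532045662677,8,subordinate
ds003,st003,species1,-18.248078965116292,119.49392261914909,scat,35,bamboo,0.48500796633531634,NA,0.28275532045662677,8,subordinate
ds003,st003,species1,-18.248078965116292,119.49392261914909,scat,35,browse_foliage,0.17896971292064892,NA,0.28275532045662677,8,subordinate
ds004,st003,species1,-33.9907979988493,61.30153424106538,scat,124,social_insects,0,0,1.210498194659339,11,subordinate
ds004,st003,species1,-33.9907979988493,61.30153424106538,scat,124,birds,0,0,1.210498194659339,11,subordinate
ds004,st003,species1,-33.9907979988493,61.30153424106538,scat,124,ungulates,0,0,1.210498194659339,11,subordinate
ds004,st003,species1,-33.9907979988493,61.30153424106538,scat,124,bamboo,0.42822991591306026,0.3410489011750023,1.210498194659339,11,subordinate
ds004,st003,species1,-33.9907979988493,61.30153424106538,scat,124,other_debris,0.37544461826644615,0.551748207314377,1.210498194659339,11,subordinate
ds004,st003,species1,-33.9907979988493,61.30153424106538,scat,124,crops,0.03681818727647345,0.02340639095606892,1.210498194659339,11,subordinate
ds004,st003,species1,-33.9907979988493,61.30153424106538,scat,124,fungi,0.060631573786202785,0.029274951780220236,1.210498194659339,11,subordinate
ds004,st003,species1,-33.9907979988493,61.30153424106538,scat,124,hard_mast,0.09887570475781736,0.05452154877433165,1.210498194659339,11,subordinate
ds005,st003,species1,28.409252467099577,174.94349948130548,scat,338,birds,0.025852085951718742,0.019229573773200257,0.48172395133808493,8,dominant
ds005,st003,species1,28.409252467099577,174.94349948130548,scat,338,social_insects,0.03586609406867362,0.024282316616308204,0.48172395133808493,8,dominant
ds005,st003,species1,28.409252467099577,174.94349948130548,scat,338,herptiles,0.02882396315411337,0.020108689486491357,0.48172395133808493,8,dominant
ds005,st003,species1,28.409252467099577,174.94349948130548,scat,338,browse_foliage,0.14125302399075784,0.14186502434992315,0.48172395133808493,8,dominant
ds005,st003,species1,28.409252467099577,174.94349948130548,scat,338,fleshy_fruits,0.020019637142229273,0.023693607561565667,0.48172395133808493,8,dominant
ds005,st003,species1,28.409252467099577,174.94349948130548,scat,338,fungi,0.5360028211042693,0.60609433681439,0.48172395133808493,8,dominant
ds005,st003,species1,28.409252467099577,174.94349948130548,scat,338,hard_mast,0.1400417315777984,0.1020587921386526,0.48172395133808493,8,dominant
ds005,st003,species1,28.409252467099577,174.94349948130548,scat,338,crops,0.07214064301043939,0.06266765925946881,0.48172395133808493,8,dominant
ds006,st004,species2,23.393202133011073,-37.63841073028743,scat,241,social_insects,0.005857619906180494,0.0016464115404336193,0.15333132134655875,4,subordinate
ds006,st004,species2,23.393202133011073,-37.63841073028743,scat,241,fish,0.019297493747468718,0.007231455525025371,0.15333132134655875,4,subordinate
ds006,st004,species2,23.393202133011073,-37.63841073028743,scat,241,small_mammals,0.008745525223070502,0.0028052297119106817,0.15333132134655875,4,subordinate
ds006,st004,species2,23.393202133011073,-37.63841073028743,scat,241,fleshy_fruits,0.15859784599816198,0.17999997742620513,0.15333132134655875,4,subordinate
ds006,st004,species2,23.393202133011073,-37.63841073028743,scat,241,other_debris,0.1836389197764984,0.1388790056448003,0.15333132134655875,4,subordinate
ds006,st004,species2,23.393202133011073,-37.63841073028743,scat,241,hard_mast,0.1710964972514756,0.10684139992273096,0.15333132134655875,4,subordinate
ds006,st004,species2,23.393202133011073,-37.63841073028743,scat,241,fungi,0.1897172045053057,0.3653351544087369,0.15333132134655875,4,subordinate
ds006,st004,species2,23.393202133011073,-37.63841073028743,scat,241,crops,0.26304889359183853,0.1972613658201571,0.15333132134655875,4,subordinate
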