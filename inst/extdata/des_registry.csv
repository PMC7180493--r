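des_id,dataset,component,role,ratio_part,n_data
DES1,test,1-ethyl-3-methylimidazolium chloride,HBA,2,5
DES1,test,ethylene glycol,HBD,1,5
DES2,training,1-ethyl-3-methylimidazolium chloride,HBA,1,5
DES2,training,ethylene glycol,HBD,1,5
DES3,test,1-ethyl-3-methylimidazolium chloride,HBA,1,5
DES3,test,ethylene glycol,HBD,2,5
DES4,training,benzyl tributyl ammonium chloride,HBA,1,13
DES4,training,ethylene glycol,HBD,3,13
DES5,training,benzyl tributyl ammonium chloride,HBA,1,13
DES5,training,diethylene glycol,HBD,3,13
DES6,training,benzyl tributyl ammonium chloride,HBA,1,13
DES6,training,triethylene glycol,HBD,3,13
DES7,test,benzyl tributyl ammonium chloride,HBA,1,13
DES7,test,glycerol,HBD,3,13
DES8,training,benzyl trimethyl ammonium chloride,HBA,1,13
DES8,training,ethylene glycol,HBD,3,13
DES9,training,benzyl trimethyl ammonium chloride,HBA,1,13
DES9,training,diethylene glycol,HBD,3,13
DES10,test,benzyl trimethyl ammonium chloride,HBA,1,13
DES10,test,triethylene glycol,HBD,3,13
DES11,training,benzyl trimethyl ammonium chloride,HBA,1,13
DES11,training,glycerol,HBD,3,13
DES12,training,benzyl tripropyl ammonium chloride,HBA,1,11
DES12,training,phenol,HBD,3,11
DES13,training,benzyl tripropyl ammonium chloride,HBA,1,11
DES13,training,ethylene glycol,HBD,3,11
DES14,training,benzyl tripropyl ammonium chloride,HBA,1,11
DES14,training,lactic acid,HBD,3,11
DES15,training,benzyl tripropyl ammonium chloride,HBA,1,11
DES15,training,glycerol,HBD,3,11
DES16,training,betaine,HBA,1,10
DES16,training,lactic acid,HBD,2,10
DES17,training,betaine,HBA,1,11
DES17,training,lactic acid,HBD,5,11
DES18,training,betaine,HBA,1,11
DES18,training,levulinic acid,HBD,2,11
DES19,training,betaine,HBA,1,11
DES19,training,lactic acid,HBD,1,11
DES19,training,water,HBD,1,11
DES20,test,betaine,HBA,2,11
DES20,test,citric acid,HBD,1,11
DES20,test,water,HBD,6,11
DES21,training,choline chloride,HBA,1,20
DES21,training,urea,HBD,2,20
DES22,test,choline chloride,HBA,1,13
DES22,test,ethylene glycol,HBD,2,13
DES23,test,choline chloride,HBA,1,38
DES23,test,glycerol,HBD,2,38
DES24,training,choline chloride,HBA,2,7
DES24,training,fructose,HBD,1,7
DES25,test,choline chloride,HBA,2,7
DES25,test,glucose,HBD,1,7
DES26,training,choline chloride,HBA,1,10
DES26,training,"1,2-propanediol",HBD,3,10
DES27,training,choline chloride,HBA,1,11
DES27,training,levulinic acid,HBD,2,11
DES28,training,choline chloride,HBA,1,7
DES28,training,malonic acid,HBD,1,7
DES29,test,choline chloride,HBA,1,7
DES29,test,glutaric acid,HBD,1,7
DES30,training,choline chloride,HBA,1,4
DES30,training,oxalic acid,HBD,1,4
DES31,training,dodecanoic acid,HBA,1,11
DES31,training,octanoic acid,HBD,3,11
DES32,training,dodecanoic acid,HBA,1,10
DES32,training,decanoic acid,HBD,2,10
DES33,training,menthol,HBA,1,11
DES33,training,octanoic acid,HBD,1,11
DES34,training,menthol,HBA,1,11
DES34,training,decanoic acid,HBD,1,11
DES35,training,menthol,HBA,4,5
DES35,training,salicylic acid,HBD,1,5
DES36,test,menthol,HBA,5,5
DES36,test,camphor-10-sulfonic acid,HBD,1,5
DES37,training,menthol,HBA,1,5
DES37,training,ethylene glycol,HBD,1,5
DES38,test,proline,HBA,1,11
DES38,test,levulinic acid,HBD,2,11
DES39,training,proline,HBA,1,10
DES39,training,lactic acid,HBD,1,10
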