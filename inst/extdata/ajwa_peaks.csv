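group,no,name,formula,observed_mz,calculated_mz,cm_printed,fragments,confidence
Phenolic acids and derivatives,1,4-Hydroxybenzoyl glucose,C13H16O8,299.0773,299.0766,299.0766,137.02;163.02,2
Phenolic acids and derivatives,2,Coumaroylshikimic acid,C16H16O7,319.0824,319.0817,319.0817,173.04;163.03;145.02,2
Phenolic acids and derivatives,3,Vanillic acid glucoside,C14H18O9,329.0873,329.0872,329.0872,167.03;152.02;123.04,2
Phenolic acids and derivatives,4,Caffeoylshikimic acid,C16H16O8,335.0776,335.0772,335.0772,179.01;161.03;155.03;137.05,2
Phenolic acids and derivatives,5,Quinic acid hexoside,C13H22O11,353.1085,353.1084,353.1084,191.05;173.04;179.05,2
Phenolic acids and derivatives,6,5-Feruloylquinic acid,C17H20O9,367.1046,367.1029,367.1029,191.08;173.04;127.01,2
Phenolic acids and derivatives,5,Caffeic acid derivatives,C18H18O9,377.0885,377.0878,377.0878,341.10;215.03;179.06;161.04;135.05,2
Phenolic acids and derivatives,6,Sinapic acid hexoside,C17H22O10,385.1141,385.1135,385.1135,223.06;205.05,2
Phenolic acids and derivatives,7,Caffeoyl shikimic acid hexoside,C22H26O13,497.1297,497.1295,497.1295,335.01;178.02;161.03;155.03;135.02,2
Phenolic acids and derivatives,8,Quinic acid derivatives,C19H34O17,533.1718,533.1718,533.1718,341.10;191.05,2
Phenolic acids and derivatives,9,1;2-di-(syringoyl)-hexoside,C24H28O14,539.1377,539.1401,539.1401,359.09;341.08;197.04;153.05,3
Flavonoids and derivatives,10,Luteolin,C15H10O6,285.0405,285.0399,285.0399,267.05;241.03;151.00;133.02,2
Flavonoids and derivatives,11,Catechin/Epicatechin,C15H14O6,289.0718,289.0712,289.0712,245.04;205.05;179;151.04;137.02,2
Flavonoids and derivatives,12,Chrysoeriol,C16H12O6,299.0561,299.0555,299.0555,285.03;153.01;135.03;125.03,2
Flavonoids and derivatives,13,Quercetin,C15H10O7,301.0354,301.0348,301.0348,273.02;229.05;179.01;151.01,2
Flavonoids and derivatives,14,Epigallocatechin,C15H14O7,305.0644,305.0661,305.0661,287.05;137.02;125.02,2
Flavonoids and derivatives,15,Methoxysinensetin,C21H22O8,401.1299,401.1236,401.1236,371.11;339.08;191.71,2
Flavonoids and derivatives,16,Epicatechin hydroxybenzoate,C22H18O8,409.0924,409.0923,409.0923,289.07;271.06;137.02;119.01,2
Flavonoids and derivatives,17,Naringenin rhamnoside,C21H22O9,417.1245,417.1186,417.1186,271.06;187.03;151.00;119.05,2
Flavonoids and derivatives,18,Epicatechin-3-gallate,C22H18O10,441.081,441.0821,441.0821,371.04;273.02;135.10;169.02,2
Flavonoids and derivatives,19,Biochanin A 7-glucoside,C22H22O10,445.1195,445.1135,445.1135,283.06;239.03;211.04;132.02,2
Flavonoids and derivatives,20,Epicatechin 3-(-methylgallate),C23H20O10,455.1015,455.0978,455.0978,289.02;183.05;124.01,2
Flavonoids and derivatives,21,Afrormosin 7-glucoside,C23H24O10,459.1354,459.1291,459.1291,297.07;281.04;267.06,2
Flavonoids and derivatives,22,Chrysoeriol hexoside,C22H22O11,461.1085,461.1083,461.1083,299.07;283.02;269.06,2
Flavonoids and derivatives,23,Isoquercitrin,C21H20O12,463.0878,463.0876,463.0876,301.05;268.01;179.02;151.01,2
Flavonoids and derivatives,24,Epicatechin 4'-glucuronide,C21H22O12,465.1036,465.1033,465.1033,289.15;151.10;137.08;123.10,2
Flavonoids and derivatives,25,Isorhamnetin hexoside,C22H22O12,477.1035,477.1033,477.1033,315.05;300.01;179.05;151.02,2
Flavonoids and derivatives,26,Luteone glucoside,C26H28O11,515.1611,515.1553,515.1553,353.10;311.05;297.04,3
Flavonoids and derivatives,27,Luteolin hexosyl sulfate,C21H20O14S,527.0491,527.0495,527.0495,447.05;285.01;241.06,2
Flavonoids and derivatives,28,Chrysoeriol hexosyl sulfate,C22H22O14S,541.0645,541.0652,541.0652,299.05;284.05;241.02,2
Flavonoids and derivatives,29,Isoquercitrin sulfate,C21H20O15S,543.0441,543.0444,543.0444,463.05;301.01;179.02;151.01,2
Flavonoids and derivatives,30,Procyanidin B2,C30H26O12,577.1347,577.1346,577.1346,451.10;407.07;289.07;287.05;125.02,2
Flavonoids and derivatives,31,Lyoniresinol 9-glucoside,C28H38O13,581.2236,581.2234,581.2234,419.17;265.10;247.09,2
Flavonoids and derivatives,32,Luteolin rhamnosyl hexoside,C27H30O15,593.1507,593.1506,593.1506,447.09;285.03;153.01;135.04,2
Flavonoids and derivatives,33,Chrysoeriol rhamnosyl hexoside,C28H32O15,607.1669,607.1663,607.1663,461.10;299.05;153.01;149.05,2
Flavonoids and derivatives,34,Isorhamnetin rhamnosyl hexoside,C28H32O16,623.1617,623.1612,623.1612,477.10;315.05;299.05;165.05,2
Flavonoids and derivatives,35,Isorhamnetin diglucoside,C28H32O17,639.1563,639.1561,639.1561,447.01;315.01,2
Flavonoids and derivatives,36,Quercetin xylosyl rutinoside,C32H38O20,741.1846,741.1878,741.1878,609.14;301.03,2
Flavonoids and derivatives,37,Luteolin rhamnosyl dihexoside,C33H40O20,755.2046,755.2034,755.2034,709.16;593.10;575.05;285.01,2
Flavonoids and derivatives,38,Quercetin glucosyl-rutinoside,C33H40O21,771.1981,771.1983,771.1983,609.14;591.05;301.03;153.02;125.00,2
Flavonoids and derivatives,39,Isorhamnetin rhamnosyl dihexoside,C34H42O21,785.211,785.214,785.214,623.16;477.10;315.05,2
Flavonoids and derivatives,40,Epicatechin-(2a-7;4a-8)-epicatechin glucoside,C36H34O17,737.1721,737.1718,737.1718,721.02;577.05;425.05;195.02,2
Sugar molecules,41,Ribonic acid,C5H10O6,165.0421,165.0399,165.0418,149.04;105.01;87.00;75.00,2
Sugar molecules,42,L-Galactose,C6H12O6,179.0572,179.0561,179.0561,161.04;143.03;113.02;101.02,2
Sugar molecules,43,Gluconic acid,C6H12O7,195.0522,195.0504,195.0504,177.05;159.02;129.05;98.90,2
Sugar molecules,48,Sedoheptulose,C7H14O7,209.0679,209.0661,209.068,191.05;179.05;149.04,2
Sugar molecules,49,Xylosmaloside,C18H20O9,379.1027,379.1029,379.1029,343.08;217.05;179.05;161.04,3
Carboxylic acids,50,Fumaric acid,C4H4O4,115.005,115.0037,115.0037,71.01,2
Carboxylic acids,51,Glutaconic acid,C5H6O4,129.0203,129.0188,129.0203,111.00;85.02,2
Carboxylic acids,52,Glutaric acid,C5H8O4,131.0355,131.035,131.035,113.00;87.02,2
Carboxylic acids,53,3-Methylglutaconic acid,C6H8O4,143.0367,143.0344,143.0361,99.03,2
Carboxylic acids,54,Methyl glutaric acid,C6H10O4,145.0521,145.0506,145.0506,127.02;101.02,2
Carboxylic acids,55,2-Hydroxyglutaric acid,C5H8O5,147.0301,147.0299,147.0299,129.01;99.03,2
Carboxylic acids,56,Hydroxymethyl glutaric acid,C6H10O5,161.0459,161.0455,161.0455,143.03;117.05;99.04,2
Carboxylic acids,58,Citric acid,C6H8O7,191.0197,191.0197,191.0197,173.00;129.01;111.00,2
Fatty acids,59,Palmitic acid,C16H32O2,255.233,255.233,255.233,237.23;211.24;197.22,2
Fatty acids,60,Linolenic acid,C18H30O2,277.2165,277.2169,277.2169,259.20;233.22;205.21;179.25,2
Fatty acids,61,a-Linoleic acid,C18H32O2,279.2331,279.2330,279.2330,261.22,2
Fatty acids,62,Oleic acid,C18H34O2,281.2487,281.2486,281.2486,263.25;181.21;127.25,2
Fatty acids,63,Hydroxy octadecatrienoic acid,C18H30O3,293.212,293.2117,293.0216,275.22,3
Fatty acids,64,Hydroxy octadecadienoic acid,C18H32O3,295.2276,295.2273,295.2273,277.23,2
Fatty acids,65,Hydroxy octadecenoic acid,C18H34O3,297.2433,297.2429,297.2429,279.23,2
Fatty acids,66,Dihydroxy octadecadienoic acid,C18H32O4,311.2246,311.2222,311.2239,293.22;275.23,2
Fatty acids,67,Dihydroxy octadecenoic acid,C18H34O4,313.2381,313.2378,313.2378,295.23;277.25;183.32,2
Fatty acids,68,Dihydroxy octadecanoic acid,C18H36O4,315.2538,315.2535,315.2535,297.23;279.25,2
Fatty acids,69,Trihydroxy octadecadienoic acid,C18H32O5,327.2176,327.2171,327.2171,309.23;291.25;273.23,2
Fatty acids,70,Trihydroxy octadecenoic acid,C18H34O5,329.2346,329.2333,329.2333,311.25;293.26;275.23,2
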