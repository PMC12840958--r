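compound_id,name,chem_class,odor_threshold,odor_desc_lit,odor_desc_exp,gco_detected,ri_exp,ri_lit,id_methods
F1,hexanal,aldehyde,4.5,"fatty, oily, grass, green","fatty, green",TRUE,791,800,MS;RI;STD;O
F2,nonanal,aldehyde,1,"green, citrus","green, citrus",TRUE,1100,1102,MS;RI;STD;O
F3,heptanal,aldehyde,3,"fresh, fruity-like, floral","sweet, fresh, fruity-like",TRUE,895,899,MS;RI;STD;O
F4,octanal,aldehyde,0.7,"fatty, grassy, lemon, green, fruity","fatty, grassy",TRUE,982,981,MS;RI;STD;O
F5,decanal,aldehyde,3.02,"green, citrus, sweet, floral, soapy","citrus, floral, soapy",TRUE,1204,1203,MS;RI;STD;O
F6,(E)-2-decenal,aldehyde,0.4,"green, waxy, fatty","waxy, fatty",TRUE,1262,1265,MS;RI;STD;O
F7,"(E,E)-2,4-decadienal",aldehyde,0.07,"fatty, waxy, nutty, melon, citrus","nutty, fatty",TRUE,1319,1320,MS;RI;STD;O
F8,2-undecenal,aldehyde,340,"sweet, fatty","sweet, fatty",TRUE,1365,1359,MS;RI;O
F9,dodecanal,aldehyde,1.07,"minty, soapy",minty,TRUE,1409,1412,MS;RI;STD;O
F10,pentadecanal,aldehyde,430,fresh,"fresh, citrus",TRUE,1719,1715,MS;RI;O
F11,hexadecanal,aldehyde,-,-,-,FALSE,1820,1822,MS;RI;STD
F12,tetradecanal,aldehyde,60,"waxy, floral","waxy, fat",TRUE,1830,1822,MS;RI;STD;O
F13,pentanal,aldehyde,12,-,-,FALSE,701,698,MS;RI
F14,octadecanal,aldehyde,91,-,-,FALSE,2027,2024,MS;RI
F15,vanillin,aldehyde,58,-,-,FALSE,1395,1394,MS;RI;STD
F16,acetoin,ketone,8000,-,-,FALSE,710,720,MS;RI;STD
F17,2-butanone,ketone,3000,-,-,FALSE,600,602,MS;RI
F18,"4,6-heptadiyn-3-one",ketone,-,-,-,FALSE,862,-,MS
F19,1-hepten-3-one,ketone,0.04,geranium-like,"geranium-like, sweet",TRUE,856,856,MS;RI;O
F20,3-methyl-3-buten-2-one,ketone,1000,-,-,FALSE,660,653,MS;RI
F21,"3,5-octadien-2-one",ketone,-,-,-,FALSE,1099,1093,MS;RI
F22,2-tridecanone,ketone,-,-,-,FALSE,1489,1494,MS;RI;STD
F23,3-methyl-cyclopentanone,ketone,-,-,-,FALSE,850,847.5,MS;RI
F24,pentanol,alcohol,4000,-,-,FALSE,771,768,MS;RI;STD
F25,3-methyl-1-butanol,alcohol,4.0,"fruity, malty",fruity,TRUE,783,779,MS;RI;STD;O
F26,2-octen-1-ol,alcohol,50,-,-,FALSE,1041,1039.7,MS;RI
F27,2-ethyl-1-butanol,alcohol,75.2,-,-,FALSE,830,830,MS;RI
F28,1-octen-3-ol,alcohol,1,"straw, earthy, raw mushroom",raw mushroom,TRUE,970,976,MS;RI;STD;O
F29,methyl stearate,ester,-,-,-,FALSE,2133,2130,MS;RI;STD
F30,ethyl octanoate,ester,650,-,-,FALSE,1195,1196,MS;RI;STD
F31,dibutyl phthalate,ester,260,-,-,FALSE,1964,1959.7,MS;RI;STD
F32,ethyl acetate,ester,100,-,-,FALSE,515,515,MS;RI;STD
F33,2-phenylethyl phenylacetate,ester,-,-,-,FALSE,1926,1924.3,MS;RI
F34,2-phenylethyl benzoate,ester,-,-,-,FALSE,1863,1858.9,MS;RI
F35,5-methyl-1-hexene,hydrocarbon,-,-,-,FALSE,653,652,MS;RI
F36,d-limonene,hydrocarbon,34,-,-,FALSE,1042,1044,MS;RI;STD
F37,dimethyl disulfide,ether,-,-,-,FALSE,741,740,MS;RI
F38,1-ethoxypentane,ether,-,-,-,FALSE,793,788,MS;RI
F39,2-pentylfuran,heterocyclic,4.8,"green, nutty, bean, beany",bean,TRUE,968,970,MS;RI;STD;O
F40,2-hexylfuran,heterocyclic,-,-,-,FALSE,1100,1096,MS;RI
F41,glutarimide,heterocyclic,-,-,-,FALSE,1156,1153.9,MS;RI;STD
F42,indole,heterocyclic,140,"sweet, burnt, floral",sweet,TRUE,1290,1293,MS;RI;STD;O
F43,2-acetyl-1-pyrroline,heterocyclic,0.1,"pandan, cooked rice, sweet, pleasant, popcorn","popcorn, cooked rice",TRUE,930,922,MS;RI;STD;O
F44,2-ethoxy-butane,other,-,-,-,FALSE,635,622,MS;RI
F45,"methyl 2,2-dimethoxyacetate",other,-,-,-,FALSE,504,-,MS
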