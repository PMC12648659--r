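cas,name,synonyms,smiles,dD,dP,dH
109-99-9,tetrahydrofuran (THF),THF;tetrahydrofuran;oxolane,C1CCOC1,16.80,5.70,8.00
141-78-6,ethyl acetate,EtOAc;ethyl ethanoate,CCOC(C)=O,15.80,5.30,7.20
67-66-3,chloroform,trichloromethane,ClC(Cl)Cl,17.80,3.10,5.70
67-64-1,acetone,propanone;2-propanone,CC(C)=O,15.50,10.40,7.00
123-91-1,"1,4-dioxane",dioxane;p-dioxane,C1COCCO1,19.00,1.80,7.40
60-29-7,diethyl ether,ether;ethoxyethane;Et2O,CCOCC,19.00,7.40,4.10
107-06-2,"1,2-dichloroethane",ethylene dichloride;EDC,ClCCCl,14.50,2.90,5.10
1330-20-7,xylene,xylenes;dimethylbenzene,Cc1ccccc1C,17.60,1.00,3.10
108-88-3,toluene,methylbenzene;toluol,Cc1ccccc1,18.00,1.40,2.00
67-63-0,isopropanol,2-propanol;IPA;isopropyl alcohol,CC(C)O,15.80,6.10,16.40
110-54-3,hexane,n-hexane,CCCCCC,14.90,0.00,0.00
64-17-5,ethanol,ethyl alcohol;EtOH,CCO,15.80,8.80,19.40
75-05-8,acetonitrile,methyl cyanide;ACN;MeCN,CC#N,15.30,18.00,6.10
7732-18-5,water,H2O;deionized water,O,15.50,16.00,42.30
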