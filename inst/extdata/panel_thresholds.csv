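panel,protein,analyte,dilution_factor,cv_max,hill_min,hill_max,lloq,uloq
1,Alpha-1-acid glycoprotein,A1AG,300000,20,0.9,1.1,12.21,50000
1,Alpha-1 antitrypsin,A1AT,300000,20,0.9,1.1,73.24,300000
1,Apolipoprotein A-I,APOA1,300000,20,0.9,1.1,244.14,1000000
1,Complement 3,CO3,300000,20,0.9,1.1,610.35,2500000
1,Haptoglobin,HPT,300000,20,0.9,1.1,488.28,2000000
2,Alpha-antichymotrypsin,AACT,5000,20,0.6,0.8,1220.7,5000000
2,Carbonic anhydrase 1,CAH1,5000,20,0.9,1.1,2.44,10000
2,Clusterin,CLUS,5000,20,0.8,1.2,244.14,1000000
2,Complement 9,CO9,5000,20,0.9,1.2,24.41,100000
2,C-reactive protein,CRP,5000,20,0.9,1.1,12.21,50000
2,Dipeptidyl peptidase IV,DPPIV,5000,20,0.9,1.1,2.44,10000
2,Serum amyloid A,SAA,5000,20,0.9,1.1,12.21,50000
2,Transferrin receptor protein,TFRC,5000,20,0.9,1.1,0.49,2000
3,Protein S100-A8/-A9,CALP,100,20,1.1,1.6,48.83,200000
3,Cathepsin D,CATD,100,20,0.9,1.1,19.53,80000
3,Growth differentiation factor 15,GDF15,100,20,0.9,1.1,0.12,500
3,Gelsolin,GELS,100,20,0.85,1.1,488.28,2000000
3,Prolyl endopeptidase FAP,SEPR,100,20,0.85,1.15,2.44,10000
3,Tissue metalloproteinase inhibitor 1,TIMP1,100,20,1.3,1.5,12.21,50000
4,Annexin A1,ANXA1,4,20,0.9,1.1,12.21,50000
4,Carcinoembryonic antigen-related cell adhesion molecule 5,CEA,4,20,0.9,1.1,24.41,100000
4,Glycine-tRNA ligase,GARS,4,20,0.9,1.1,122.07,500000
4,Macrophage migration inhibitory factor,MIF,4,20,0.9,1.1,14.65,60000
4,Trefoil factor 3,TFF3,4,20,0.9,1.1,0.49,2000
5,Pyruvate kinase isozyme M2,PKM2,4,20,0.9,1.2,7812.5,2000000
5,Peroxiredoxin-1,PRDX1,4,20,0.9,1.1,12.21,50000
5,P-selectin glycoprotein ligand 1,PSGL,4,20,0.9,1.1,12.21,50000
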