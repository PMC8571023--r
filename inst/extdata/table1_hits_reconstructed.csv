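id,name,smiles
1,Unithiol,OS(=O)(=O)CC(S)CS
2,Aurotioprol,OC(CS(=O)(=O)O)CS[Au]
3,Acamprosate,CC(=O)NCCCS(=O)(=O)O
4,Menadione bisulfite,CC1(S(=O)(=O)O)CC(=O)c2ccccc2C1=O
5,Docusate sodium,CCCCC(CC)COC(=O)CC(S(=O)(=O)[O-])C(=O)OCC(CC)CCCC.[Na+]
6,Camphotamide,C[n+]1cccc(C(N)=O)c1.CC1(C)C2CCC1(CS(=O)(=O)[O-])C(=O)C2
7,Dermatan sulfate,CC(=O)NC1C(O)OC(CO)C(OC2OC(C(O)C(O)C2O)C(=O)O)C1OS(=O)(=O)O
8,Ecamsule,CC1(C)C2CCC1(CS(=O)(=O)O)C(=O)C2=Cc1ccc(C=C2C(=O)C3(CS(=O)(=O)O)CCC2C3(C)C)cc1
9,Sulfamazone,CC1=NN(c2ccccc2)C(=O)C1N(CS(=O)(=O)O)c1ccc(S(=O)(=O)Nc2nc3ccccc3s2)cc1
10,Cefpimizole,OC(=O)C(NC(=O)c1c[nH]c2ncnc(c12)N)c1ccccc1C(=O)NC1C2SCC(=C(N2C1=O)C(=O)O)C[n+]1ccc(CCS(=O)(=O)[O-])cc1
11,Glucosulfone,OCC(O)C(O)C(O)C(O)C(Nc1ccc(cc1)S(=O)(=O)c1ccc(cc1)NC(C(O)C(O)C(O)C(O)CO)S(=O)(=O)O)S(=O)(=O)O
12,Solasulfone,OS(=O)(=O)CC(CC(c1ccccc1)S(=O)(=O)O)Nc1ccc(S(=O)(=O)c2ccc(NC(CC(CS(=O)(=O)O)S(=O)(=O)O)c3ccccc3)cc2)cc1
13,Indocyanine green,CC1(C)c2ccc3ccccc3c2N(CCCCS(=O)(=O)O)C1=CC=CC=CC=C1N(CCCCS(=O)(=O)[O-])c2c(ccc3ccccc23)C1(C)C
14,TRA,NCCCS(=O)(=O)O
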