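C1CN=C(N1)Cc1cccc2ccccc12	Naphazoline
C1CN=C(N1)C1CCCc2ccccc21	Tetrahydrozoline
Cc1cc(C(C)(C)C)c(O)c(C)c1CC1=NCCN1	Oxymetazoline
CN(C)CCC(c1ccccc1)c1ccccn1	Pheniramine
C(N(Cc1ccccc1)c1ccccc1)C1=NCCN1	Antazoline
CCOCCn1c(N2CCCN(C)CC2)nc2ccccc21	Emedastine
Nc1ncnc2c1ncn2C1OC(CO)C(O)C1O	Vidarabine
OC(=O)P(=O)(O)O	Foscarnet
OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O	Ciprofloxacin
COc1c(N2CC3CCCNC3C2)c(F)cc2c(=O)c(C(=O)O)cn(C3CC3)c12	Moxifloxacin
COc1c(N2CCNC(C)C2)c(F)cc2c(=O)c(C(=O)O)cn(C3CC3)c12	Gatifloxacin
CC1COc2c(N3CCN(C)CC3)c(F)cc3c(=O)c(C(=O)O)cn1c23	Ofloxacin
NCC1OC(OC2C(N)CC(N)C(OC3OC(CO)C(O)C(N)C3O)C2O)C(N)CC1O	Tobramycin
CC1C(NC(=O)C(N)c2ccc(O)cc2)C(=O)N1C(C(=O)O)C(C)(C)S	Amoxicillin
CC1CC2C3CCC4=CC(=O)C=CC4(C)C3(F)C(O)CC2(C)C1(O)C(=O)CO	Dexamethasone
OCC(NC(=O)C(Cl)Cl)C(O)c1ccc(cc1)[N+](=O)[O-]	Chloramphenicol
OC(=O)c1cn(C2CC2)c2c(Cl)c(N3CCCCC(N)C3)c(F)cc2c1=O	Besifloxacin
CN(C)CCOC(=O)C(c1ccccc1)C1(O)CCCC1	Cyclopentolate
NC(=O)Cc1cccc(C(=O)c2ccccc2)c1N	Nepafenac
CCC1OC(=O)C(C)C(OC2CC(C)(OC)C(O)C(C)O2)C(C)C(OC2OC(C)CC(N(C)C)C2O)C(C)(O)CC(C)CN(C)C(C)C(O)C1(C)O	Azithromycin
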