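sub_id,smiles,role,feature
methyl,C,plain,
ethyl,CC,plain,
propyl,CCC,plain,
isopropyl,C(C)C,plain,
tbutyl,C(C)(C)C,plain,
methoxy,OC,plain,
ethoxy,OCC,plain,
hydroxyl,O,plain,
amino,N,plain,
methylamino,NC,plain,
dimethylamino,N(C)C,plain,
fluoro,F,plain,
chloro,Cl,plain,
bromo,Br,plain,
trifluoromethyl,C(F)(F)F,plain,
nitrile,C#N,plain,
acetyl,C(=O)C,plain,
ester,C(=O)OC,plain,
carboxyl,C(=O)O,plain,
amide,C(=O)N,plain,
thiomethyl,SC,plain,
isobutoxy,OCC(C)C,plain,
nitro,[N+](=O)[O-],plain,
phenoxy,Oc1ccccc1,plain,
benzyl,Cc1ccccc1,plain,
hydroxyethyl,CCO,plain,
sulfonamide,S(=O)(=O)N,pharmacophore,pharm_sulfonamide
methylsulfonyl,S(=O)(=O)C,pharmacophore,pharm_methylsulfonyl
piperidinyl,N1CCCCC1,pharmacophore,pharm_piperidinyl
morpholinyl,N1CCOCC1,pharmacophore,pharm_morpholinyl
thiourea,NC(=S)N,toxicophore,frag_thiourea
nitroso,N(C)N=O,toxicophore,frag_nitroso
thiophosphate,OP(=S)(OC)OC,toxicophore,frag_thiophosphate
gem_dihalo,CC(Cl)(Cl)C,toxicophore,frag_gem_dihalo
thiocarbonyl,C(=S)N(C)C,toxicophore,frag_thiocarbonyl
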