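scaffold_id,template,set
benzene,c1cc(%s)ccc1%s,core
pyridine,c1cc(%s)cnc1%s,core
pyrimidine,c1nc(%s)cc(%s)n1,core
furan,c1oc(%s)cc1%s,core
thiophene,c1sc(%s)cc1%s,core
pyrrole,c1cc(%s)c(%s)[nH]1,core
imidazole,c1nc(%s)c(%s)[nH]1,core
naphthalene,c1ccc2cc(%s)c(%s)cc2c1,core
cyclohexane,C1CC(%s)CCC1%s,core
cyclopentane,C1CC(%s)CC1%s,core
piperidine,C1CC(%s)CCN1%s,core
morpholine,O1CCN(%s)CC1%s,core
tetrahydrofuran,C1CC(%s)C(%s)O1,core
pyrazine,c1nc(%s)cnc1%s,core
benzofuran,c1cc2c(cc1%s)cc(%s)o2,core
chain10,CCCCCC(%s)CCCC%s,exotic
peg,COCCOCC(%s)OCCOC%s,exotic
fluorochain,FC(F)(F)CCC(%s)CC(F)(F)%s,exotic
branched,CC(C)CC(C)(%s)CC(C)C%s,exotic
thioether,CCSCCC(%s)CCSCC%s,exotic
aminochain,CCNCCC(%s)CCNCC%s,exotic
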