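alert_id,smarts,severity,description,source_label
AL_PS,[#15]=[#16],high,Double P=S bond (organothiophosphate-like reactive phosphorus),packaged
AL_THIOUREA,NC(=S)N,high,Thiourea,packaged
AL_NITROSO,[NX3][NX2]=O,high,N-Nitroso group,packaged
AL_THIOCARBONYL,[#6]=[SX1],moderate,Thiocarbonyl,packaged
AL_GEMDIHALO,[CX4](Cl)(Cl),moderate,Gem-dihalo propane and cyclopropane,packaged
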