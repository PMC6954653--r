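iscn,parsable,DiploidKaryotype,MaleKaryotype,FemaleKaryotype,NumericalAbnormalKaryotype,NumericalAbnormalAutosomalGain,NumericalAbnormalAutosomalLoss,NumericalAbnormalAllosomalGain,NumericalAbnormalAllosomalLoss,StructuralAbnormalKaryotype,StructuralAbnormalDeletion,StructuralAbnormalTranslocation
"46,XY",true,true,true,false,false,false,false,false,false,false,false,false
"46,XX",true,true,false,true,false,false,false,false,false,false,false,false
"46,XN",true,true,false,false,false,false,false,false,false,false,false,false
"45,X,-Y",true,true,true,false,true,false,false,false,true,false,false,false
"45,X",true,true,false,false,true,false,false,false,true,false,false,false
"47,XX,+21",true,true,false,true,true,true,false,false,false,false,false,false
"45,XY,-21",true,true,true,false,true,false,true,false,false,false,false,false
"47,XXY",true,true,true,false,true,false,false,true,false,false,false,false
"46,XY,del(15)(q11q12)",true,true,true,false,false,false,false,false,false,true,true,false
"46,XX,t(2;5)(q21;q31)",true,true,false,true,false,false,false,false,false,true,false,true
"69,XXY",true,false,true,false,false,false,false,false,false,false,false,false
"46,XX,inv(2)(p21q31)",true,true,false,true,false,false,false,false,false,true,false,false
"46,XY,der(1)t(1;5)(p22;q31)",true,true,true,false,false,false,false,false,false,true,false,true
"47,XY,+mar",true,true,true,false,false,false,false,false,false,false,false,false
"45,XY,del(21)",true,true,true,false,true,false,true,false,false,false,false,false
"abc",false,,,,,,,,,,,
"47,XY",false,,,,,,,,,,,
"46,XY,del(15)(q99q12)",false,,,,,,,,,,,
"46,XY,t(2;5)(q21)",false,,,,,,,,,,,
"46,XX/47,XX,+21",false,,,,,,,,,,,
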