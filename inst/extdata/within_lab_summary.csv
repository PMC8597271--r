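analyte,sample,n,mean_conc,sd,cv_printed
KIM1,P1,100,3048,300.2,9.8
KIM1,P2,100,1488,137.3,9.2
KIM1,P3,100,752,72.6,9.7
KIM1,P4,100,390,34.6,8.9
KIM1,P5,100,212,19.0,8.9
KIM1,P6,100,127,16.6,13.1
KIM1,P7,100,77,8.2,10.7
KIM1,P8,100,32,4.1,12.9
sTNFR1,P1,100,NA,NA,NA
sTNFR1,P2,100,NA,NA,NA
sTNFR1,P3,100,13014,1487.7,11.4
sTNFR1,P4,100,6881,613.7,8.9
sTNFR1,P5,100,4057,341.7,8.4
sTNFR1,P6,100,2742,302.6,11.0
sTNFR1,P7,100,1999,126.9,6.3
sTNFR1,P8,100,1326,85.5,6.4
sTNFR2,P1,100,50477,4175.7,8.3
sTNFR2,P2,100,26216,1889.1,7.2
sTNFR2,P3,100,15126,1125.0,7.4
sTNFR2,P4,100,9732,719.0,7.4
sTNFR2,P5,100,7177,528.4,7.4
sTNFR2,P6,100,6107,592.1,9.7
sTNFR2,P7,100,5216,387.0,7.4
sTNFR2,P8,100,4551,355.1,7.8
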