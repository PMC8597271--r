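analyte,sample,n,mean_conc,sd,cv_printed
KIM1,R1,80,3633,98.7,2.7
KIM1,R2,80,1957,65.0,3.3
KIM1,R3,80,1177,34.5,2.9
KIM1,R4,80,669,22.8,3.4
KIM1,R5,80,443,18.0,4.1
KIM1,R6,80,109,3.3,3.0
KIM1,R7,80,24,0.8,3.2
sTNFR1,R1,80,18550,1062.5,5.7
sTNFR1,R2,80,17364,1420.8,8.2
sTNFR1,R3,80,10214,396.1,3.9
sTNFR1,R4,80,4970,269.3,5.4
sTNFR1,R5,80,3415,138.1,4.0
sTNFR1,R6,80,2359,90.8,3.8
sTNFR1,R7,80,1541,63.6,4.1
sTNFR2,R1,80,50809,1886.8,3.7
sTNFR2,R2,80,34280,1207.4,3.5
sTNFR2,R3,80,30055,984.3,3.3
sTNFR2,R4,80,23239,663.0,2.9
sTNFR2,R5,80,15150,414.3,2.7
sTNFR2,R6,80,7727,202.7,2.6
sTNFR2,R7,80,6057,148.1,2.4
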