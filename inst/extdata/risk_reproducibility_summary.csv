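sample,category,n,mean_probability,sd,cv_printed
Sample1,low,20,0.138,0.002,1.4
Sample2,intermediate,20,0.215,0.022,10.4
Sample3,intermediate,20,0.178,0.012,7.0
Sample4,intermediate,20,0.209,0.001,0.3
Sample5,intermediate,20,0.169,0.008,4.7
Sample6,intermediate,20,0.164,0.001,0.8
Sample7,intermediate,20,0.197,0.013,6.6
Sample8,high,20,0.424,0.026,6.2
Sample9,high,20,0.366,0.016,4.3
Sample10,high,20,0.295,0.014,4.8
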