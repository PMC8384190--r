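site,n_days,k600,k600_se,gpp,gpp_se,er,er_se,nep,nep_se
U-A-0,153,6.9,0.3,4.7,0.2,-6.1,0.3,-1.4,0.2
U-A-2.5,178,5.9,0.3,2.5,0.2,-4.0,0.2,-1.2,0.2
D-A-4,134,6.1,0.4,3.9,0.4,-6.5,0.3,-2.0,0.3
D-A-5.5,253,7.1,0.3,2.7,0.1,-4.0,0.1,-1.3,0.1
U-B-12,263,10.2,0.3,2.3,0.1,-3.1,0.1,-0.5,0.1
D-B-14.5,119,11.0,0.6,7.4,0.6,-10.5,0.4,-2.1,0.5
D-B-15.5,89,4.8,0.3,3.3,0.3,-3.7,0.3,-0.1,0.2
D-All-16.5,307,4.8,0.2,4.7,0.3,-5.8,0.2,-0.6,0.2
D-All-33.5,294,6.3,0.2,3.0,0.1,-3.4,0.1,-0.2,0.1
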