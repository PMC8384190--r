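site,latitude,longitude,distance_km,pil_pct,pil_se_pct,width_m,width_se_m,depth_m,velocity_ms
U-A-0,40.20677,-75.29545,0,57.4,15.6,3.6,0.7,0.26,0.008
U-A-2.5,40.19009,-75.28426,2.5,29.8,4.9,7.9,1.3,0.24,0.044
D-A-4,40.18797,-75.27029,4,42.2,6.2,9.8,0.6,0.35,0.103
D-A-5.5,40.18638,-75.25479,5.5,24.6,7.5,13.9,1.2,0.34,0.014
U-B-12,40.14707,-75.22565,12,30.3,3.3,14.5,1.4,0.23,0.076
D-B-14.5,40.13957,-75.21677,14.5,41.0,6.7,16.3,1.6,0.45,0.009
D-B-15.5,40.13123,-75.22167,15.5,40.3,1.9,18.9,1.2,0.40,0.025
D-All-16.5,40.12403,-75.21918,16.5,46.9,2.2,17.7,1.9,0.48,0.101
D-All-33.5,40.01736,-75.20292,33.5,NA,NA,34.8,0.9,0.42,0.123
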