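genotype,organ,egsh_mv,sd_mv,letters
Col-0,cotyledon,-302.27,4.66,d
gpxl1,cotyledon,-274.25,11.92,a
gpxl2,cotyledon,-294.59,2.76,c
gpxl3,cotyledon,-285.03,3.06,b
gpxl4,cotyledon,-298.93,6.89,cd
gpxl5,cotyledon,-298.46,4.96,cd
gpxl6,cotyledon,-287.90,6.88,b
gpxl7,cotyledon,-277.97,3.36,a
gpxl8,cotyledon,-284.01,8.28,ab
Col-0,root,-302.48,5.88,c
gpxl1,root,-269.30,1.02,a
gpxl2,root,-289.84,4.01,b
gpxl3,root,-296.69,1.76,c
gpxl4,root,-271.86,9.25,a
gpxl5,root,-298.77,4.30,c
gpxl6,root,-278.71,8.39,a
gpxl7,root,-300.50,0.89,c
gpxl8,root,-281.32,6.43,ab
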