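category,f_low_hz,f_high_hz,colour,placeholder
blue,15,30,#67000d,TRUE
fin,15,30,#a50f15,TRUE
sei,30,100,#cb181d,TRUE
right,50,300,#ef3b2c,TRUE
humpback,100,2000,#fb6a4a,TRUE
blainville,25000,50000,#00441b,TRUE
cuvier,30000,45000,#006d2c,TRUE
gervais,35000,55000,#238b45,TRUE
true,40000,55000,#41ab5d,TRUE
sowerby,60000,90000,#74c476,TRUE
bw_mixed,35000,55000,#a1d99b,TRUE
kogia,100000,150000,#54278f,TRUE
risso,30000,90000,#756bb1,TRUE
sperm,2000,20000,#9e9ac8,TRUE
delphinid,10000,100000,#6baed6,TRUE
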