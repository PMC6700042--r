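hospital,n_total,n_complete,n_male,n_female,age_mean,age_sd,n_missing_age,n_missing_kps,n_resection,n_biopsy,deaths_30d,observable_30d,survivors_2y,observable_2y,academic,median_os_months
a,81,77,49,32,64.6,10.8,1,3,60,21,6,77,3,67,TRUE,10.2
b,229,228,152,77,60.5,13.3,0,1,175,54,6,228,36,210,TRUE,11.4
c,293,277,178,114,63.6,11.9,0,16,192,101,18,277,39,255,TRUE,10.0
d,97,95,61,36,54.6,14.7,1,1,23,62,4,95,18,78,TRUE,14.9
e,161,116,97,63,60.3,11.9,0,45,49,42,10,116,11,105,TRUE,7.4
f,269,268,172,94,60.6,12.6,0,1,187,68,10,268,30,236,TRUE,10.8
g,197,196,127,70,60.8,12.2,1,0,154,43,10,196,28,183,TRUE,9.5
h,91,82,58,33,62.9,10.2,0,1,65,25,6,82,7,78,FALSE,10.3
i,103,102,55,48,61.2,12.5,0,0,72,31,6,102,0,12,FALSE,5.2
j,233,232,145,88,61.7,11.8,1,0,179,54,9,232,32,211,FALSE,10.7
k,103,103,64,39,64.8,10.8,0,0,44,58,6,103,5,91,FALSE,4.8
l,121,111,55,47,59.7,12.7,0,9,102,19,11,111,16,93,FALSE,12.0
m,73,73,44,29,59.0,13.0,0,0,53,20,3,73,8,65,FALSE,12.1
n,358,348,219,136,62.0,10.9,6,4,209,147,14,348,37,317,FALSE,10.3
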