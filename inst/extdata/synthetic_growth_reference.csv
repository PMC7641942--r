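sex,gestational_week,mean_g,sd_g
female,30,1570,160
female,31,1732,188
female,32,1900,216
female,33,2072,244
female,34,2250,272
female,35,2432,300
female,36,2620,328
female,37,2812,356
female,38,3010,384
female,39,3212,412
female,40,3420,440
female,41,3632,468
female,42,3850,496
female,43,4072,524
male,30,1700,160
male,31,1862,188
male,32,2030,216
male,33,2202,244
male,34,2380,272
male,35,2562,300
male,36,2750,328
male,37,2942,356
male,38,3140,384
male,39,3342,412
male,40,3550,440
male,41,3762,468
male,42,3980,496
male,43,4202,524
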