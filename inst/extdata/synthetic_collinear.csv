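"y","x1","x2","x3","x4"
0.980384,0.611359,0.439678,0.383565,0.513605
-2.300514,-0.55443,-1.279913,-0.722188,-1.355152
-3.845464,-1.8093,-1.299896,-2.35619,-1.133886
-1.102785,-0.770562,-0.724692,-0.728376,-0.506452
-3.661145,-1.498329,-1.716058,-1.774854,-1.50271
3.426432,1.352685,1.200142,1.720368,1.353336
-2.644574,-1.135594,-1.721743,-1.711523,-1.28135
-2.017191,-0.882036,-0.561237,-0.929532,-0.741166
-1.111791,-0.311795,-0.013362,-0.184597,-0.601891
-3.114516,-1.83067,-1.747987,-1.403217,-1.489611
1.769125,0.659952,0.769057,0.983798,0.978207
0.773179,0.188197,0.523883,0.596512,0.323593
0.160016,-0.534497,-0.538867,-0.233567,0.027351
-0.604724,0.479817,-0.129075,0.156277,-0.035524
-1.375235,0.011508,-0.412079,-0.647016,-0.819712
-0.915811,-0.165796,-0.551628,-0.466206,-0.835655
-1.444978,-0.860505,-0.693417,-0.617939,-0.522738
-1.444447,-0.842117,-1.134719,-0.895297,-0.678971
-3.309557,-1.427577,-1.825697,-1.967905,-1.903358
-0.153092,-0.46248,-0.00373,-0.181261,-0.295917
-4.411411,-2.226414,-2.342045,-2.144234,-1.827345
-3.610728,-2.242084,-2.538687,-1.829205,-2.541687
4.380778,2.298184,2.668697,2.081679,2.491972
-1.741453,-0.386851,-0.812964,-0.71376,-0.33447
-1.051104,-0.248318,-0.170476,-0.467932,-0.019546
-2.237827,-0.779674,-1.014374,-1.673001,-1.421971
2.482677,1.429666,1.003626,1.419148,1.12719
-0.184403,-0.654704,-0.143623,-0.329742,-0.456
1.205614,0.765007,1.026743,0.543341,0.645645
0.868717,0.704627,0.433516,0.827431,0.169422
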