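# excitation_nm=355
# temperature_C=37
wavelength_nm,intensity
390,13.3074155004315
392,18.0075761449769
394,24.0688563782417
396,31.775648091333
398,41.4354728316435
400,53.3690302134061
402,67.8962423283941
404,85.3182565700963
406,105.895752355664
408,129.824352206145
410,157.208428485284
412,188.03507317981
414,222.150397956313
416,259.240589438585
418,298.820198496436
420,340.229944668762
422,382.645843740969
424,425.100725556536
426,466.51824370709
428,505.758367274527
430,541.672194752291
432,573.162866769026
434,599.248504727862
436,619.122579528026
438,632.206999379911
440,638.193535283544
442,637.069962493409
444,629.12842040207
446,614.95487220369
448,595.40004024781
450,571.533652542432
452,544.585117850795
454,515.874734324119
456,486.740151287192
458,458.463012415273
460,432.200522512435
462,408.926148729216
464,389.382866377903
466,374.051379124781
468,363.134673847569
470,356.559193502488
472,353.991893731559
474,354.871540815068
476,358.451845192802
478,363.853430256046
480,370.121227515377
482,376.28367947823
484,381.410130065829
486,384.662993463311
488,385.341711617582
490,382.916121170127
492,377.047619517719
494,367.597397075063
496,354.621923912833
498,338.356769368278
500,319.19061682246
502,297.631943951926
504,274.271219235066
506,249.741589783019
508,224.68090266316
510,199.69753831212
512,175.341990526831
514,152.08546948742
516,130.306106290264
518,110.282671348841
520,92.1951458232017
522,76.1310489975728
524,62.0961488709828
526,50.0280711416062
528,39.8113581085446
530,31.292685062296
532,24.2951808069032
534,18.6310821393537
536,14.1122432584411
538,10.5582905096114
540,7.80243952828104
542,5.69516386233992
544,4.10601818124686
546,2.9239787533063
548,2.05667733374147
550,1.42888292161724
552,0.980540670331415
554,0.66461941355696
556,0.444957827215978
558,0.294240923595315
560,0.192187740414259
562,0.123989999038632
564,0.0790107155067226
566,0.0497305988501714
568,0.0309171700810412
570,0.0189851542414303
572,0.011515077648047
574,0.0068985522235314
576,0.00408213520653647
578,0.00238591603640923
580,0.00137740377501305
582,0.000785426812204803
584,0.000442372903402222
586,0.000246098888606457
588,0.000135228779319306
590,7.33950791667347e-05
592,3.93462275059909e-05
594,2.08342367158663e-05
596,1.08965854677926e-05
598,5.62913423033426e-06
600,2.87230874079644e-06
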