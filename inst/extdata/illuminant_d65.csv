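"wavelength_nm","relative_power"
300,0.0341
301,0.36014
302,0.68618
303,1.01222
304,1.33826
305,1.6643
306,1.99034
307,2.31638
308,2.64242
309,2.96846
310,3.2945
311,4.98864
312,6.68278
313,8.37692
314,10.0711
315,11.7652
316,13.4594
317,15.1535
318,16.8477
319,18.5418
320,20.236
321,21.9177
322,23.5995
323,25.2812
324,26.963
325,28.6447
326,30.3265
327,32.0082
328,33.69
329,35.3717
330,37.0535
331,37.343
332,37.6325
333,37.9221
334,38.2116
335,38.5011
336,38.7906
337,39.0802
338,39.3697
339,39.6593
340,39.9488
341,40.4451
342,40.9414
343,41.4376
344,41.9339
345,42.4302
346,42.9265
347,43.4228
348,43.9191
349,44.4154
350,44.9117
351,45.0844
352,45.257
353,45.4297
354,45.6023
355,45.775
356,45.9477
357,46.1203
358,46.293
359,46.4656
360,46.6383
361,47.1834
362,47.7285
363,48.2735
364,48.8186
365,49.3637
366,49.9088
367,50.4539
368,50.9989
369,51.544
370,52.0891
371,51.8777
372,51.6664
373,51.455
374,51.2437
375,51.0323
376,50.8209
377,50.6096
378,50.3982
379,50.1869
380,49.9755
381,50.4428
382,50.91
383,51.3773
384,51.8445
385,52.3118
386,52.7791
387,53.2464
388,53.7136
389,54.1809
390,54.6482
391,57.4589
392,60.2695
393,63.0802
394,65.8908
395,68.7015
396,71.5122
397,74.3229
398,77.1335
399,79.9442
400,82.7549
401,83.628
402,84.5011
403,85.3742
404,86.2473
405,87.1204
406,87.9935
407,88.8666
408,89.7398
409,90.6129
410,91.486
411,91.6806
412,91.8752
413,92.0697
414,92.2643
415,92.4589
416,92.6535
417,92.8481
418,93.0426
419,93.2372
420,93.4318
421,92.7568
422,92.0819
423,91.4069
424,90.732
425,90.057
426,89.3821
427,88.7071
428,88.0322
429,87.3572
430,86.6823
431,88.5006
432,90.3188
433,92.1371
434,93.9553
435,95.7736
436,97.5919
437,99.4102
438,101.228
439,103.047
440,104.865
441,106.079
442,107.293
443,108.508
444,109.722
445,110.936
446,112.15
447,113.365
448,114.579
449,115.794
450,117.008
451,117.088
452,117.169
453,117.249
454,117.33
455,117.41
456,117.49
457,117.571
458,117.651
459,117.732
460,117.812
461,117.517
462,117.222
463,116.926
464,116.631
465,116.336
466,116.041
467,115.746
468,115.451
469,115.156
470,114.861
471,114.967
472,115.073
473,115.18
474,115.286
475,115.392
476,115.498
477,115.604
478,115.711
479,115.817
480,115.923
481,115.212
482,114.501
483,113.789
484,113.078
485,112.367
486,111.656
487,110.945
488,110.233
489,109.522
490,108.811
491,108.865
492,108.919
493,108.974
494,109.028
495,109.082
496,109.136
497,109.191
498,109.245
499,109.3
500,109.354
501,109.199
502,109.044
503,108.888
504,108.733
505,108.578
506,108.423
507,108.268
508,108.112
509,107.957
510,107.802
511,107.501
512,107.2
513,106.898
514,106.597
515,106.296
516,105.995
517,105.694
518,105.392
519,105.091
520,104.79
521,105.08
522,105.37
523,105.659
524,105.949
525,106.239
526,106.529
527,106.819
528,107.109
529,107.399
530,107.689
531,107.361
532,107.032
533,106.704
534,106.375
535,106.047
536,105.719
537,105.39
538,105.062
539,104.733
540,104.405
541,104.369
542,104.333
543,104.297
544,104.261
545,104.225
546,104.189
547,104.153
548,104.118
549,104.082
550,104.046
551,103.641
552,103.237
553,102.832
554,102.428
555,102.023
556,101.618
557,101.214
558,100.809
559,100.405
560,100
561,99.6334
562,99.2668
563,98.9003
564,98.5337
565,98.1671
566,97.8005
567,97.4339
568,97.0674
569,96.7008
570,96.3342
571,96.2796
572,96.225
573,96.1703
574,96.1157
575,96.0611
576,96.0065
577,95.9519
578,95.8972
579,95.8426
580,95.788
581,95.0778
582,94.3675
583,93.6573
584,92.947
585,92.2368
586,91.5266
587,90.8163
588,90.1061
589,89.3958
590,88.6856
591,88.8177
592,88.9497
593,89.0818
594,89.2138
595,89.3459
596,89.478
597,89.61
598,89.7421
599,89.8741
600,90.0062
601,89.9655
602,89.9248
603,89.884
604,89.8433
605,89.8026
606,89.7619
607,89.7212
608,89.6805
609,89.6398
610,89.5991
611,89.4091
612,89.219
613,89.029
614,88.8389
615,88.6489
616,88.4589
617,88.2688
618,88.0788
619,87.8887
620,87.6987
621,87.2577
622,86.8167
623,86.3756
624,85.9346
625,85.4936
626,85.0526
627,84.6116
628,84.1706
629,83.7296
630,83.2886
631,83.3297
632,83.3707
633,83.4118
634,83.4528
635,83.4939
636,83.535
637,83.576
638,83.6171
639,83.6581
640,83.6992
641,83.332
642,82.9647
643,82.5975
644,82.2302
645,81.863
646,81.4958
647,81.1285
648,80.7613
649,80.394
650,80.0268
651,80.0456
652,80.0644
653,80.0831
654,80.1019
655,80.1207
656,80.1395
657,80.1583
658,80.177
659,80.1958
660,80.2146
661,80.4209
662,80.6272
663,80.8336
664,81.0399
665,81.2462
666,81.4525
667,81.6588
668,81.8652
669,82.0715
670,82.2778
671,81.8784
672,81.4791
673,81.0797
674,80.6804
675,80.281
676,79.8816
677,79.4823
678,79.0829
679,78.6836
680,78.2842
681,77.4279
682,76.5716
683,75.7153
684,74.859
685,74.0027
686,73.1464
687,72.2901
688,71.4339
689,70.5776
690,69.7213
691,69.9101
692,70.0989
693,70.2876
694,70.4764
695,70.6652
696,70.854
697,71.0428
698,71.2315
699,71.4203
700,71.6091
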