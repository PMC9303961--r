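# Published descriptive counts for a 62,870-case lung-cancer registry
# series (three prefectures, 1993-2015) by sex and period of diagnosis.
# The histology margin partitions cases into the six groups plus the two
# nonspecific morphology codes; the stage margin into the three summary
# stages plus unknown and missing.
margin,sex,period,category,count
histology,male,1993-1999,SMC,1206
histology,male,2000-2004,SMC,988
histology,male,2005-2009,SMC,1060
histology,male,2010-2015,SMC,1339
histology,male,1993-1999,SQC,3001
histology,male,2000-2004,SQC,2273
histology,male,2005-2009,SQC,2536
histology,male,2010-2015,SQC,3140
histology,male,1993-1999,ADC,3403
histology,male,2000-2004,ADC,3103
histology,male,2005-2009,ADC,3732
histology,male,2010-2015,ADC,5106
histology,male,1993-1999,LAC,304
histology,male,2000-2004,LAC,203
histology,male,2005-2009,LAC,194
histology,male,2010-2015,LAC,213
histology,male,1993-1999,other_nsclc,107
histology,male,2000-2004,other_nsclc,71
histology,male,2005-2009,other_nsclc,156
histology,male,2010-2015,other_nsclc,269
histology,male,1993-1999,other_unspec,1753
histology,male,2000-2004,other_unspec,1551
histology,male,2005-2009,other_unspec,1737
histology,male,2010-2015,other_unspec,2030
histology,male,1993-1999,code_8010,1006
histology,male,2000-2004,code_8010,883
histology,male,2005-2009,code_8010,949
histology,male,2010-2015,code_8010,1255
histology,male,1993-1999,code_8046,27
histology,male,2000-2004,code_8046,143
histology,male,2005-2009,code_8046,195
histology,male,2010-2015,code_8046,180
histology,female,1993-1999,SMC,214
histology,female,2000-2004,SMC,165
histology,female,2005-2009,SMC,201
histology,female,2010-2015,SMC,242
histology,female,1993-1999,SQC,318
histology,female,2000-2004,SQC,250
histology,female,2005-2009,SQC,271
histology,female,2010-2015,SQC,384
histology,female,1993-1999,ADC,2243
histology,female,2000-2004,ADC,2161
histology,female,2005-2009,ADC,2645
histology,female,2010-2015,ADC,3914
histology,female,1993-1999,LAC,72
histology,female,2000-2004,LAC,51
histology,female,2005-2009,LAC,30
histology,female,2010-2015,LAC,29
histology,female,1993-1999,other_nsclc,35
histology,female,2000-2004,other_nsclc,32
histology,female,2005-2009,other_nsclc,38
histology,female,2010-2015,other_nsclc,83
histology,female,1993-1999,other_unspec,735
histology,female,2000-2004,other_unspec,658
histology,female,2005-2009,other_unspec,735
histology,female,2010-2015,other_unspec,967
histology,female,1993-1999,code_8010,514
histology,female,2000-2004,code_8010,466
histology,female,2005-2009,code_8010,519
histology,female,2010-2015,code_8010,626
histology,female,1993-1999,code_8046,10
histology,female,2000-2004,code_8046,51
histology,female,2005-2009,code_8046,59
histology,female,2010-2015,code_8046,39
stage,male,1993-1999,localized,1766
stage,male,2000-2004,localized,1596
stage,male,2005-2009,localized,2227
stage,male,2010-2015,localized,3678
stage,male,1993-1999,regional,2904
stage,male,2000-2004,regional,2290
stage,male,2005-2009,regional,2840
stage,male,2010-2015,regional,3209
stage,male,1993-1999,distant,2864
stage,male,2000-2004,distant,2359
stage,male,2005-2009,distant,3251
stage,male,2010-2015,distant,4840
stage,male,1993-1999,unknown,1773
stage,male,2000-2004,unknown,1642
stage,male,2005-2009,unknown,1330
stage,male,2010-2015,unknown,1150
stage,male,1993-1999,missing,1500
stage,male,2000-2004,missing,1328
stage,male,2005-2009,missing,911
stage,male,2010-2015,missing,655
stage,female,1993-1999,localized,929
stage,female,2000-2004,localized,979
stage,female,2005-2009,localized,1413
stage,female,2010-2015,localized,2442
stage,female,1993-1999,regional,852
stage,female,2000-2004,regional,730
stage,female,2005-2009,regional,853
stage,female,2010-2015,regional,932
stage,female,1993-1999,distant,1017
stage,female,2000-2004,distant,945
stage,female,2005-2009,distant,1149
stage,female,2010-2015,distant,1955
stage,female,1993-1999,unknown,707
stage,female,2000-2004,unknown,613
stage,female,2005-2009,unknown,568
stage,female,2010-2015,unknown,546
stage,female,1993-1999,missing,636
stage,female,2000-2004,missing,567
stage,female,2005-2009,missing,515
stage,female,2010-2015,missing,409
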