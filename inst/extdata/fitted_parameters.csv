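product,temperature_C,model,param,value
C. morifolium flower,5,henderson,a0,9.8934
C. morifolium flower,5,henderson,a1,0.8358
C. morifolium flower,15,henderson,a0,10.1609
C. morifolium flower,15,henderson,a1,0.9196
C. morifolium flower,25,henderson,a0,10.1559
C. morifolium flower,25,henderson,a1,0.8595
C. morifolium flower,35,henderson,a0,10.4075
C. morifolium flower,35,henderson,a1,0.9956
C. morifolium flower,45,henderson,a0,10.8141
C. morifolium flower,45,henderson,a1,1.0105
C. morifolium flower,5,chung_pfost,b0,5.508
C. morifolium flower,5,chung_pfost,b1,-6.112
C. morifolium flower,15,chung_pfost,b0,5.7531
C. morifolium flower,15,chung_pfost,b1,-6.411
C. morifolium flower,25,chung_pfost,b0,5.896
C. morifolium flower,25,chung_pfost,b1,-6.082
C. morifolium flower,35,chung_pfost,b0,5.926
C. morifolium flower,35,chung_pfost,b1,-6.602
C. morifolium flower,45,chung_pfost,b0,6.129
C. morifolium flower,45,chung_pfost,b1,-6.7451
C. morifolium flower,5,halsey,c0,5.9427
C. morifolium flower,5,halsey,c1,1.5704
C. morifolium flower,15,halsey,c0,5.7082
C. morifolium flower,15,halsey,c1,0.6639
C. morifolium flower,25,halsey,c0,5.9209
C. morifolium flower,25,halsey,c1,0.6126
C. morifolium flower,35,halsey,c0,5.4476
C. morifolium flower,35,halsey,c1,0.7576
C. morifolium flower,45,halsey,c0,5.5654
C. morifolium flower,45,halsey,c1,0.7842
C. morifolium flower,5,oswin,d0,7.3971
C. morifolium flower,5,oswin,d1,0.4731
C. morifolium flower,15,oswin,d0,7.3641
C. morifolium flower,15,oswin,d1,0.5396
C. morifolium flower,25,oswin,d0,7.5094
C. morifolium flower,25,oswin,d1,0.4994
C. morifolium flower,35,oswin,d0,7.2905
C. morifolium flower,35,oswin,d1,0.6045
C. morifolium flower,45,oswin,d0,7.5193
C. morifolium flower,45,oswin,d1,0.6214
C. morifolium flower,5,white_eirig,e0,0.2472
C. morifolium flower,5,white_eirig,e1,-0.2208
C. morifolium flower,15,white_eirig,e0,0.256
C. morifolium flower,15,white_eirig,e1,-0.2389
C. morifolium flower,25,white_eirig,e0,0.2483
C. morifolium flower,25,white_eirig,e1,-0.2263
C. morifolium flower,35,white_eirig,e0,0.2698
C. morifolium flower,35,white_eirig,e1,-0.2632
C. morifolium flower,45,white_eirig,e0,0.2648
C. morifolium flower,45,white_eirig,e1,-0.2116
C. morifolium flower,5,caurie,f0,1.8739
C. morifolium flower,5,caurie,f1,2.6012
C. morifolium flower,15,caurie,f0,1.6968
C. morifolium flower,15,caurie,f1,2.7997
C. morifolium flower,25,caurie,f0,1.8784
C. morifolium flower,25,caurie,f1,2.6398
C. morifolium flower,35,caurie,f0,1.5901
C. morifolium flower,35,caurie,f1,2.9493
C. morifolium flower,45,caurie,f0,1.6464
C. morifolium flower,45,caurie,f1,2.9602
C. morifolium flower,5,gab,A,6.1289
C. morifolium flower,5,gab,B,1.3142
C. morifolium flower,5,gab,C,0.6442
C. morifolium flower,15,gab,A,2.8515
C. morifolium flower,15,gab,B,2.0917
C. morifolium flower,15,gab,C,0.7811
C. morifolium flower,25,gab,A,2.8434
C. morifolium flower,25,gab,B,2.1447
C. morifolium flower,25,gab,C,0.7457
C. morifolium flower,35,gab,A,1.4477
C. morifolium flower,35,gab,B,3.3973
C. morifolium flower,35,gab,C,0.8807
C. morifolium flower,45,gab,A,3.1852
C. morifolium flower,45,gab,B,1.9537
C. morifolium flower,45,gab,C,0.8257
A. formosanus Hayata,5,henderson,a0,11.1085
A. formosanus Hayata,5,henderson,a1,1.0682
A. formosanus Hayata,15,henderson,a0,11.2013
A. formosanus Hayata,15,henderson,a1,1.1939
A. formosanus Hayata,25,henderson,a0,11.7819
A. formosanus Hayata,25,henderson,a1,1.0687
A. formosanus Hayata,35,henderson,a0,11.9449
A. formosanus Hayata,35,henderson,a1,1.1718
A. formosanus Hayata,45,henderson,a0,12.1878
A. formosanus Hayata,45,henderson,a1,1.1162
A. formosanus Hayata,5,chung_pfost,b0,4.1801
A. formosanus Hayata,5,chung_pfost,b1,-9.563
A. formosanus Hayata,15,chung_pfost,b0,4.1701
A. formosanus Hayata,15,chung_pfost,b1,-10.0561
A. formosanus Hayata,25,chung_pfost,b0,5.1377
A. formosanus Hayata,25,chung_pfost,b1,-9.328
A. formosanus Hayata,35,chung_pfost,b0,5.422
A. formosanus Hayata,35,chung_pfost,b1,-9.368
A. formosanus Hayata,45,chung_pfost,b0,5.813
A. formosanus Hayata,45,chung_pfost,b1,-8.993
A. formosanus Hayata,5,halsey,c0,6.36
A. formosanus Hayata,5,halsey,c1,0.6749
A. formosanus Hayata,15,halsey,c0,5.6542
A. formosanus Hayata,15,halsey,c1,0.8224
A. formosanus Hayata,25,halsey,c0,6.2743
A. formosanus Hayata,25,halsey,c1,0.7433
A. formosanus Hayata,35,halsey,c0,5.7114
A. formosanus Hayata,35,halsey,c1,0.8781
A. formosanus Hayata,45,halsey,c0,5.9771
A. formosanus Hayata,45,halsey,c1,0.8446
A. formosanus Hayata,5,oswin,d0,7.9799
A. formosanus Hayata,5,oswin,d1,0.5792
A. formosanus Hayata,15,oswin,d0,7.5396
A. formosanus Hayata,15,oswin,d1,0.6871
A. formosanus Hayata,25,oswin,d0,8.1977
A. formosanus Hayata,25,oswin,d1,0.6177
A. formosanus Hayata,35,oswin,d0,7.8989
A. formosanus Hayata,35,oswin,d1,0.7013
A. formosanus Hayata,45,oswin,d0,8.1917
A. formosanus Hayata,45,oswin,d1,0.6802
A. formosanus Hayata,5,white_eirig,e0,0.2248
A. formosanus Hayata,5,white_eirig,e1,-0.2099
A. formosanus Hayata,15,white_eirig,e0,0.2476
A. formosanus Hayata,15,white_eirig,e1,-0.2434
A. formosanus Hayata,25,white_eirig,e0,0.2266
A. formosanus Hayata,25,white_eirig,e1,-0.2172
A. formosanus Hayata,35,white_eirig,e0,0.2492
A. formosanus Hayata,35,white_eirig,e1,-0.2522
A. formosanus Hayata,45,white_eirig,e0,0.2394
A. formosanus Hayata,45,white_eirig,e1,-0.2396
A. formosanus Hayata,5,caurie,f0,1.3805
A. formosanus Hayata,5,caurie,f1,3.2662
A. formosanus Hayata,15,caurie,f0,1.1989
A. formosanus Hayata,15,caurie,f1,3.5179
A. formosanus Hayata,25,caurie,f0,1.5561
A. formosanus Hayata,25,caurie,f1,3.185
A. formosanus Hayata,35,caurie,f0,1.3618
A. formosanus Hayata,35,caurie,f1,3.4184
A. formosanus Hayata,45,caurie,f0,1.5218
A. formosanus Hayata,45,caurie,f1,3.2744
A. formosanus Hayata,5,gab,A,156146.6
A. formosanus Hayata,5,gab,B,0.007007
A. formosanus Hayata,5,gab,C,0.5401
A. formosanus Hayata,15,gab,A,9696.467
A. formosanus Hayata,15,gab,B,0.0269
A. formosanus Hayata,15,gab,C,0.5952
A. formosanus Hayata,25,gab,A,11806.88
A. formosanus Hayata,25,gab,B,0.0269
A. formosanus Hayata,25,gab,C,0.5232
A. formosanus Hayata,35,gab,A,7.9452
A. formosanus Hayata,35,gab,B,1.0877
A. formosanus Hayata,35,gab,C,0.8255
A. formosanus Hayata,45,gab,A,65.9138
A. formosanus Hayata,45,gab,B,0.3634
A. formosanus Hayata,45,gab,C,0.6303
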