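patient_id,aneurysm_id,size_mm,location,shape,ruptured,age_years,smoker,hypertension,site,treatment,published_score
p01,p01a1,7,MCA,irregular,1,NA,NA,NA,MCA_left,surgical,0.4321
p01,p01a2,3,ACOM_AA,regular,0,NA,NA,NA,AcomA,none,0.1281
p02,p02a1,6,PCOM,regular,1,NA,NA,NA,PcomA,surgical,0.0216
p02,p02a2,2,POSTERIOR,regular,0,NA,NA,NA,basilar_tip,none,-0.0977
p03,p03a1,7,MCA,regular,1,NA,NA,NA,MCA_left,surgical,-0.1066
p03,p03a2,5,MCA,regular,0,NA,NA,NA,MCA_right,none,-0.192
p04,p04a1,6,PCOM,irregular,1,NA,NA,NA,PcomA,endovascular,0.7845
p04,p04a2,3,ACOM_AA,regular,0,NA,NA,NA,A3,none,0.1281
p05,p05a1,7,ACOM_AA,irregular,1,NA,NA,NA,AcomA,endovascular,0.8376
p05,p05a2,7,PCOM,regular,0,NA,NA,NA,PcomA,combined,0.2885
p05,p05a3,6,MCA,regular,0,NA,NA,NA,MCA,none,-0.1493
p05,p05a4,3,ACOM_AA,regular,0,NA,NA,NA,A1,endovascular,0.1281
p05,p05a5,4,ICA_WO_PCOM,regular,0,NA,NA,NA,ICA,none,-0.4265
p05,p05a6,2,POSTERIOR,regular,0,NA,NA,NA,P1,none,-0.0977
p05,p05a7,3,POSTERIOR,regular,0,NA,NA,NA,basilar_tip,none,-0.0556
p06,p06a1,10,POSTERIOR,regular,1,NA,NA,NA,basilar_tip,endovascular,0.2439
p06,p06a2,3,POSTERIOR,regular,0,NA,NA,NA,basilar_side,none,-0.0557
p07,p07a1,6,PCOM,irregular,1,NA,NA,NA,PcomA,endovascular,0.7845
p07,p07a2,4,MCA,regular,0,NA,NA,NA,MCA,none,-0.2347
p08,p08a1,5,ACOM_AA,regular,1,NA,NA,NA,AcomA,endovascular,0.2135
p08,p08a2,2,MCA,regular,0,NA,NA,NA,MCA,none,-0.3201
p09,p09a1,5,ACOM_AA,irregular,1,NA,NA,NA,AcomA,surgical,0.7522
p09,p09a2,13,MCA,regular,0,NA,NA,NA,MCA,surgical,0.1496
p10,p10a1,3,ACOM_AA,regular,1,NA,NA,NA,AcomA,endovascular,0.1281
p10,p10a2,2,MCA,regular,0,NA,NA,NA,MCA,none,-0.3201
p11,p11a1,17,MCA,regular,1,NA,NA,NA,MCA_left,surgical,0.3204
p11,p11a2,7,MCA,regular,0,NA,NA,NA,MCA_right,none,-0.1066
p12,p12a1,6,POSTERIOR,irregular,1,NA,NA,NA,basilar_tip,endovascular,0.6118
p12,p12a2,3,PCOM,regular,0,NA,NA,NA,PcomA,endovascular_staged,0.1177
p13,p13a1,3,ACOM_AA,regular,1,NA,NA,NA,AcomA,endovascular,0.1281
p13,p13a2,3,PCOM,regular,0,NA,NA,NA,PcomA,endovascular,0.1177
p13,p13a3,2,ICA_WO_PCOM,regular,0,NA,NA,NA,ophthalmic,none,-0.5119
p13,p13a4,2,POSTERIOR,regular,0,NA,NA,NA,VA,none,-0.0977
p14,p14a1,4,ACOM_AA,regular,1,NA,NA,NA,A3,endovascular,0.1708
p14,p14a2,3,MCA,regular,0,NA,NA,NA,MCA,none,-0.2774
p14,p14a3,1,MCA,regular,0,NA,NA,NA,MCA,none,-0.3628
p15,p15a1,8,PCOM,regular,1,NA,NA,NA,PcomA_right,surgical,0.3312
p15,p15a2,4,PCOM,regular,0,NA,NA,NA,PcomA_left,none,0.1604
p16,p16a1,10,MCA,regular,1,NA,NA,NA,MCA_left,surgical,0.0215
p16,p16a2,2,MCA,regular,0,NA,NA,NA,MCA_right,none,-0.3201
p17,p17a1,5,POSTERIOR,regular,1,NA,NA,NA,PICA_left,endovascular,0.0304
p17,p17a2,2,POSTERIOR,regular,0,NA,NA,NA,SCA_left,none,-0.0977
p18,p18a1,9,POSTERIOR,regular,1,NA,NA,NA,VB_junction,endovascular,0.2012
p18,p18a2,4,ACOM_AA,regular,0,NA,NA,NA,AcomA,none,0.1708
p18,p18a3,2,ACOM_AA,regular,0,NA,NA,NA,A2,none,0.0854
p19,p19a1,4,MCA,regular,1,NA,NA,NA,MCA_right,none,-0.2347
p19,p19a2,2,MCA,regular,0,NA,NA,NA,MCA_left,none,-0.3201
p20,p20a1,8,MCA,irregular,1,NA,NA,NA,MCA,surgical,0.4748
p20,p20a2,4,ICA_WO_PCOM,regular,0,NA,NA,NA,ICA,none,-0.4265
p20,p20a3,3,ACOM_AA,regular,0,NA,NA,NA,A3,none,0.1281
p21,p21a1,5,MCA,regular,1,NA,NA,NA,MCA_left,surgical,-0.192
p21,p21a2,5,MCA,regular,0,NA,NA,NA,MCA_right,none,-0.192
p22,p22a1,9,MCA,irregular,1,NA,NA,NA,MCA_left,surgical,0.5175
p22,p22a2,9,MCA,regular,0,NA,NA,NA,MCA_right,surgical_staged,-0.0212
p23,p23a1,9,ACOM_AA,irregular,1,NA,NA,NA,AcomA,endovascular,0.923
p23,p23a2,7,ICA_WO_PCOM,regular,0,NA,NA,NA,ICA,none,-0.2984
p24,p24a1,6,POSTERIOR,irregular,0,NA,NA,NA,basilar_tip,endovascular,0.6118
p24,p24a2,10,MCA,regular,1,NA,NA,NA,MCA_right,surgical,0.0215
p25,p25a1,8,MCA,regular,1,NA,NA,NA,MCA_right,surgical,-0.0639
p25,p25a2,4,MCA,regular,0,NA,NA,NA,MCA_left,none,-0.2347
p25,p25a3,4,ICA_WO_PCOM,regular,0,NA,NA,NA,ICA_left,none,-0.4265
p26,p26a1,7,MCA,regular,1,NA,NA,NA,MCA_right,surgical,-0.1066
p26,p26a2,2,MCA,regular,0,NA,NA,NA,M2_right,surgical,-0.3201
p26,p26a3,3,MCA,regular,0,NA,NA,NA,MCA_left,none,-0.2774
p27,p27a1,7,PCOM,regular,1,NA,NA,NA,PcomA_left,endovascular,0.2885
p27,p27a2,7,ICA_WO_PCOM,regular,0,NA,NA,NA,ICA_right,endovascular,-0.2984
p28,p28a1,10,MCA,regular,1,NA,NA,NA,M2_right,surgical,0.0215
p28,p28a2,6,ICA_WO_PCOM,regular,0,NA,NA,NA,ICA_left,none,-0.3411
p28,p28a3,3,MCA,regular,0,NA,NA,NA,M2_left,none,-0.2774
p29,p29a1,9,ICA_WO_PCOM,regular,1,NA,NA,NA,ICA,endovascular,-0.213
p29,p29a2,3,MCA,regular,0,NA,NA,NA,MCA,none,-0.2774
p30,p30a1,10,PCOM,regular,1,NA,NA,NA,PcomA,endovascular,0.4166
p30,p30a2,4,ACOM_AA,regular,0,NA,NA,NA,AcomA,none,0.1708
p31,p31a1,11,ACOM_AA,regular,1,NA,NA,NA,AcomA,endovascular,0.4697
p31,p31a2,5,PCOM,regular,0,NA,NA,NA,PcomA,none,0.2031
p32,p32a1,9,ACOM_AA,regular,1,NA,NA,NA,ACA_A3,endovascular,0.3843
p32,p32a2,3,MCA,regular,0,NA,NA,NA,MCA_left,none,-0.2774
p32,p32a3,2,ICA_WO_PCOM,regular,0,NA,NA,NA,ICA_left,none,-0.5119
p32,p32a4,6,POSTERIOR,regular,0,NA,NA,NA,SCA_right,none,0.0731
p33,p33a1,5,ACOM_AA,regular,1,NA,NA,NA,AcomA,endovascular,0.2135
p33,p33a2,3,MCA,regular,0,NA,NA,NA,M3_right,surgical,-0.2774
p34,p34a1,9,PCOM,regular,1,NA,NA,NA,PcomA_right,surgical,0.3739
p34,p34a2,6,ICA_WO_PCOM,regular,0,NA,NA,NA,ICA_left,none,-0.3411
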