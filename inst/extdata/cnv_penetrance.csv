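cnv_label,locus_hg19,n_study,age_mean,age_sd,n_male,n_female,p_sz,p_dd,transcription_uncertain
15q11.2 BP1-2 deletion,chr15:22805313-23094530,2,48.4,2.3,1,1,2,11,dd
15q13.3 BP4-5 deletion,chr15:31080645-32462776,2,30.0,4.5,2,0,4.7,35,
15q13.3 BP4-5 duplication,chr15:31080645-32462776,1,41.7,NA,1,0,1.8,8,
16p11.2 distal duplication,chr16:28823196-29046783,1,40.3,NA,0,1,0.7,5.3,
16p11.2 deletion,chr16:29650840-30200773,1,43.0,NA,1,0,0.5,31,sz
17q12 duplication,chr17:34815904-36217432,1,47.1,NA,0,1,1.7,17,
1q21.1 deletion,chr1:146527987-147394444,4,35.0,15.0,4,0,5.2,35,
1q21.1 duplication,chr1:146527987-147394444,1,39.5,NA,0,1,2.9,18,
22q11.2 deletion,chr22:19037332-21466726,4,31.2,17.0,2,2,12,88,
22q11.2 duplication,chr22:19037332-21466726,2,44.9,4.8,1,1,0,14,
3q29 deletion,chr3:195720167-197354826,1,19.9,NA,1,0,18,53,
NRXN1 deletion,chr2:50145643-51259674,1,43.6,NA,1,0,6.4,26,
control,,15,39.6,11.3,6,9,0,0,
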