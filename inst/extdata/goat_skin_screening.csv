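gene,type,mean_fpkm,cv_pct,cv_rank_all,mfc,dpm
RRAGA,new,51.4,8.4,6,1.416,0.083
PTPRA,new,23.8,9.1,8,1.474,0.090
SRP68,new,27.2,9.2,9,1.510,0.091
EIF4H,new,133.0,9.5,16,1.479,0.094
NCBP3,new,10.0,9.5,17,1.542,0.094
CTBP2,new,22.5,9.9,25,1.566,0.098
CNBP,new,226.5,14.3,458,1.880,0.141
EEF2,new,499.7,15.1,619,1.923,0.149
SDHA,previous,44.0,18.5,1679,2.710,0.182
YWHAZ,previous,137.5,19.2,1946,2.320,0.189
ACTB,conventional,556.1,24.6,4456,2.962,0.239
GAPDH,conventional,391.6,29.9,6855,2.945,0.286
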