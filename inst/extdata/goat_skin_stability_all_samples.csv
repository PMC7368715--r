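gene,normfinder,normfinder_rank,bestkeeper_std,bestkeeper_rank,delta_ct,delta_ct_rank,genorm_rank,comprfinder_fs,comprfinder_rank
NCBP3,0.011,2,0.753,3,0.512,4,3,0.096,1
SDHA,0.009,1,0.733,2,0.503,3,NA,0.099,2
PTPRA,0.012,3,0.779,7,0.499,1,1,0.108,3
EEF2,0.012,4,0.775,6,0.500,2,NA,0.129,4
EIF4H,0.014,6,0.768,5,0.520,5,2,0.143,5
SRP68,0.016,9,0.663,1,0.590,9,NA,0.192,6
CTBP2,0.013,5,0.764,4,0.553,6,NA,0.248,7
YWHAZ,0.015,7,0.871,9,0.557,7,NA,0.311,8
RRAGA,0.015,8,0.811,8,0.568,8,NA,0.320,9
GAPDH,0.018,10,0.984,11,0.741,10,10,0.603,10
CNBP,0.021,11,0.962,10,0.757,11,11,0.680,11
ACTB,0.026,12,1.114,12,0.973,12,12,1.000,12
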