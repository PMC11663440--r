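id,sex,age_years,age_basis,side,femur_length_mm,voxel_size_mm,stage
MPITC_11787,M,0.04,documented,L,63.1,0.015,1
MPITC_15015,NA,0.18,documented,R,71.3,0.014,1
MPITC_15003,NA,0.64,length_estimated,R,88.6,0.016,2
MPITC_14993,F,0.74,documented,R,102.5,0.058,2
MPITC_15000,NA,1.23,documented_year,R,105.6,0.058,2
MPITC_13432,M,1.77,documented,R,121.5,0.015,2
MPITC_11777,M,2.13,documented,R,125.4,0.015,2
MPITC_11788,F,3.76,documented,R,164.2,0.055,3
MPITC_14995,M,5.24,documented,L,174.7,0.091,4
MPITC_14992,NA,5.84,length_estimated,R,186.7,0.091,4
MPITC_11791,F,6.45,documented,L,192.1,0.091,4
MPITC_15011,M,6.63,documented_year,R,173.3,0.091,4
MPITC_13433,M,7.61,documented,L,228.0,0.091,4
MPITC_11782,M,8.34,documented_year,L,209.8,0.091,4
MPITC_15020,F,9.98,documented,L,223.5,0.091,4
MPITC_13437,F,11.4,documented,R,240.9,0.091,5
MPITC_11776,F,12.38,documented_year,R,245.4,0.091,5
MPITC_11779,M,12.57,documented_year,L,268.5,0.091,5
NHM_Z.D.1846.10.23.11,NA,3.99,length_estimated,R,163.1,0.044,3
NHM_Z.D.1976.436,F,11.26,length_estimated,R,239.7,0.065,5
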