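sequence,plane,cr_time,dlr_time
T2,ax,2:47,0:42
T2,cor,3:11,0:50
T1CEfs,ax,2:43,1:07
T1CEfs,cor,5:06,1:38
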