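nucleotide,templating_base,motif,helper_present,temperature_c,kd_mM,censored,pairing,method
T,A,2a,FALSE,20,260,FALSE,complementary,nmr
T,A,3a,FALSE,20,280,FALSE,complementary,nmr
T,A,4a,FALSE,20,240,FALSE,complementary,nmr
G,C,2c,FALSE,20,10,FALSE,complementary,nmr
G,C,3c,FALSE,20,16,FALSE,complementary,nmr
G,T,4t,FALSE,20,100,FALSE,wobble,nmr
C,G,2g,FALSE,20,40,FALSE,complementary,nmr
C,T,4t,FALSE,20,2000,TRUE,mismatch,nmr
A,T,4t,FALSE,20,38,FALSE,complementary,nmr
rG,rC,6c,FALSE,20,14,FALSE,complementary,nmr
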