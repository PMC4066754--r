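nucleotide,templating_base,motif,helper_present,temperature_c,kd_mM,censored,pairing,method
T,A,TAT,TRUE,20,59,FALSE,complementary,inhibition
G,C,TCT,TRUE,20,2,FALSE,complementary,inhibition
C,G,TGT,TRUE,20,5,FALSE,complementary,inhibition
A,T,TTT,TRUE,20,5,FALSE,complementary,inhibition
T,A,GAG,TRUE,20,83,FALSE,complementary,inhibition
G,C,GCG,TRUE,20,10,FALSE,complementary,inhibition
C,G,GGG,TRUE,20,18,FALSE,complementary,inhibition
A,T,GTG,TRUE,20,5,FALSE,complementary,inhibition
T,A,CAC,TRUE,20,113,FALSE,complementary,inhibition
G,C,CCC,TRUE,20,7,FALSE,complementary,inhibition
C,G,CGC,TRUE,20,6,FALSE,complementary,inhibition
A,T,CTC,TRUE,20,7,FALSE,complementary,inhibition
T,A,AAA,TRUE,20,77,FALSE,complementary,inhibition
G,C,ACA,TRUE,20,5,FALSE,complementary,inhibition
C,G,AGA,TRUE,20,15,FALSE,complementary,inhibition
A,T,ATA,TRUE,20,5,FALSE,complementary,inhibition
T,A,TAT,FALSE,20,200,FALSE,complementary,inhibition
G,C,TCT,FALSE,20,15,FALSE,complementary,inhibition
C,G,TGT,FALSE,20,19,FALSE,complementary,inhibition
A,T,TTT,FALSE,20,17,FALSE,complementary,inhibition
T,A,CAC,FALSE,10,144,FALSE,complementary,inhibition
G,C,CCC,FALSE,10,5,FALSE,complementary,inhibition
C,G,CGC,FALSE,10,30,FALSE,complementary,inhibition
A,T,CTC,FALSE,10,7,FALSE,complementary,inhibition
C,G,TGT,FALSE,10,10,FALSE,complementary,inhibition
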