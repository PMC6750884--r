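subject,session,phase,trial,a1,s2,a2,outcome,transition,aborted,rt
s1,1,probe,0,L,S2,R,1,common,0,0.41
s1,1,probe,1,L,S1,R,0,rare,0,0.38
s1,1,probe,2,R,S1,L,0,common,0,
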