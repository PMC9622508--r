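period,mean_activity_level
1970s,0.19
current,0.41
2050s,0.55
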