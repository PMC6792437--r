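name	seq
synth_f1	TGYGAYCCNAARGCNGA
synth_r1	ADNGCCATCATYTCNCC
synth_f2	GGHAARGGHGGHATHGGNAA
synth_r2	GGCATNGCRAANCCVCCRCANAC
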