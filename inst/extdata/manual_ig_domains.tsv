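id	start	end	region
Ig_man_01	2704	2794	I-band
Ig_man_02	3145	3233	I-band
Ig_man_03	9581	9670	I-band
Ig_man_04	12041	12133	I-band
Ig_man_05	12321	12411	I-band
Ig_man_06_I91	12674	12765	I-band
Ig_man_07	12854	12943	I-band
Ig_man_08	13030	13119	I-band
Ig_man_09	13837	13926	I-band
Ig_man_10	14319	14411	I-band
Ig_man_11	20618	20710	A-band
Ig_man_12	31553	31646	M-band
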