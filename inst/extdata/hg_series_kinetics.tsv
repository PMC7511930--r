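variant	mutations	design_sites	kcat_km	kcat_km_err
HG3			146	6
HG3.3b	V6I K50H M84C S89R Q90D A125N	K50H M84C Q90D A125N	2200	100
HG3.7	V6I Q37K K50Q M84C S89R Q90H A125N	K50Q M84C Q90H A125N	27000	2000
HG3.14	V6I Q37K K50Q G82A M84C Q90H T105I A125T T142N T208M T279S D300N	K50Q M84C Q90H A125T	52000	1000
HG3.17	V6I Q37K N47E K50Q G82A M84C S89N Q90F T105I A125T T142N T208M F267M W275A R276F T279S D300N	N47E K50Q M84C Q90F A125T F267M W275A R276F	126000	9000
HG4	K50Q G82A M84C Q90F A125T F267M W275A R276F	K50Q M84C Q90F A125T F267M W275A R276F	103000	4000
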