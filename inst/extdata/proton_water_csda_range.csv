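# CSDA range of protons in liquid water, standard reference values.
# energy in MeV; range in g/cm^2 (equals cm at density 1 g/cm^3).
energy_MeV,csda_range_g_cm2
10,0.1230
20,0.4260
30,0.8853
40,1.489
50,2.227
60,3.093
70,4.080
80,5.184
90,6.398
100,7.718
150,15.77
200,25.96
250,37.94
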