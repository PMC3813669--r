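year,population,child_population,physicians,pediatricians
1996,124900000,19700000,230297,13781
1998,125600000,19100000,236933,13989
2000,126100000,18600000,243201,14160
2002,126500000,18100000,249574,14481
2004,126800000,17800000,256668,14677
2006,127100000,17500000,263540,14700
2008,127100000,17300000,271897,15236
2010,127100000,17100000,280431,15870
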