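year,sex,departure_md,departure_sd_days,departure_n,arrival_md,arrival_sd_days,arrival_n
2009,F,08-22,0,2,,,
2009,M,08-16,,1,,,
2010,F,08-21,4.6,4,05-20,4,2
2010,M,08-17,10,2,05-15,1,2
2011,F,08-11,2,2,05-24,,1
2011,M,07-31,,1,05-06,,1
2012,F,08-06,,1,05-17,,1
2012,M,07-25,,1,,,
2013,F,08-07,2.5,6,05-08,7,4
2013,M,07-30,8,2,05-03,,1
overall,F,08-10,7.5,15,05-16,7.1,8
overall,M,08-03,11.1,7,05-10,5.5,4
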