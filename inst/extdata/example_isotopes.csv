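"tree_id","site_id","year","d13c_raw_permil"
"site1-P1","site1",1917,-20.766
"site1-P1","site1",1927,-20.702
"site1-P1","site1",1931,-21.139
"site1-P1","site1",1942,-22.055
"site1-P2","site1",1917,-21.52
"site1-P2","site1",1927,-20.16
"site1-P2","site1",1931,-20.742
"site1-P2","site1",1942,-22.284
"site1-M1","site1",1959,-22.295
"site1-M1","site1",1982,-23.227
"site1-M1","site1",1986,-22.867
"site1-M1","site1",1997,-23.677
"site1-M2","site1",1959,-23.719
"site1-M2","site1",1982,-21.339
"site1-M2","site1",1986,-24.577
"site1-M2","site1",1997,-23.604
"site2-P1","site2",1910,-22.128
"site2-P1","site2",1933,-23.576
"site2-P1","site2",1935,-24.569
"site2-P1","site2",1946,-24.493
"site2-P2","site2",1910,-23.061
"site2-P2","site2",1933,-23.447
"site2-P2","site2",1935,-23.191
"site2-P2","site2",1946,-23.361
"site2-M1","site2",1965,-21.479
"site2-M1","site2",1969,-20.882
"site2-M1","site2",1970,-21.634
"site2-M1","site2",1973,-22.267
"site2-M2","site2",1965,-23.451
"site2-M2","site2",1969,-22.815
"site2-M2","site2",1970,-21.872
"site2-M2","site2",1973,-20.539
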