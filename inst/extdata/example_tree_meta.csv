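"tree_id","site_id","census_dbh_cm","census_year","structure"
"t001","site1",34.8,2015,"savanna"
"t002","site1",39,2015,"savanna"
"t003","site1",30.8,2015,"savanna"
"t004","site2",31.2,2015,"forest"
"t005","site2",37.2,2015,"forest"
"t006","site2",29.5,2015,"forest"
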