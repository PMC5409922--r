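year,n_detected_total,n_primary,n_secondary,n_unclassified,n_active_primary_destroyed,n_active_secondary_destroyed,n_inactive_secondary_detected
2007,4,0,0,4,0,1,3
2008,27,0,0,27,0,12,15
2009,83,38,45,0,18,14,31
2010,61,25,36,0,4,18,18
2011,77,26,51,0,11,22,29
2012,94,34,60,0,16,34,26
2013,90,29,61,0,24,39,22
2014,111,12,99,0,0,79,20
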