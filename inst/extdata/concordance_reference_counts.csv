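stratum,buffer,ema_at_home_gps_at_home,ema_not_home_gps_at_home,ema_at_home_gps_not_home,ema_not_home_gps_not_home,n_not_matched
urban,20,927,107,91,569,439
urban,50,966,68,101,559,439
urban,100,974,60,103,557,439
non_urban,20,286,63,29,232,153
non_urban,50,319,30,34,227,153
non_urban,100,342,7,35,226,153
android,20,506,93,36,305,162
android,50,551,48,43,298,162
android,100,564,35,45,296,162
ios,20,707,77,84,496,430
ios,50,734,50,92,488,430
ios,100,752,32,93,487,430
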