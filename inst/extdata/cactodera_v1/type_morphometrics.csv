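stage,character,holotype,mean,sd,lo,hi,n,note
cyst,cyst_length,531,571.2,79.1,511.0,761.0,20,
cyst,cyst_width,429,454.3,56.8,360.5,558.0,20,
cyst,cyst_lw_ratio,1.23,1.3,0.1,1.1,1.6,20,holotype prints 1.23 although 531/429 = 1.2378 rounds to 1.24; printed value kept
cyst,fenestral_diam,22.8,23.4,3.8,20.0,31.5,20,
J2,j2_length,,538.5,25.0,494.5,591.5,20,
J2,j2_width,,23.2,1.4,20.0,25.0,20,
J2,a_ratio,,23.4,2.0,20.6,27.2,20,
J2,b_ratio,,3.7,0.3,3.1,4.2,20,pharynx length itself is not tabulated; b not recomputable from this table
J2,c_ratio,,10.0,0.8,8.4,11.6,20,
J2,c_prime,,3.9,0.3,3.5,4.5,20,
J2,lip_height,,4.8,0.4,4.0,5.0,20,
J2,lip_diam,,10.7,0.8,9.0,12.0,20,
J2,stylet_length,,24.9,0.8,22.5,26.0,20,
J2,stylet_base_height,,2.5,0.3,2.0,3.0,20,
J2,stylet_base_width,,5.1,0.54,4.0,5.5,20,
J2,mb,,77.8,4.2,69.5,85.0,20,
J2,dgo,,4.9,0.5,4.0,6.5,20,
J2,ep,,111.2,6.2,97.5,124.0,20,
J2,mbw,,11.8,1.1,9.5,13.5,20,
J2,anal_diam,,13.8,0.5,11.5,15.0,20,
J2,tail_length,,54.1,3.6,46.5,59.0,20,
J2,hyaline_length,,25.8,2.1,21.5,28.5,20,
J2,l_over_mb,,6.9,0.5,6.1,8.0,20,
J2,tl_over_h,,2.1,0.2,1.8,2.4,20,
egg,egg_length,,117.9,11.6,101.5,144.0,20,
egg,egg_width,,51.3,4.1,41.0,61.5,20,
egg,egg_lw_ratio,,2.3,0.3,1.9,2.9,20,
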