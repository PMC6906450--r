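event_id,det,E_MeV,t_ns,x_cm,y_cm,z_cm
1,3,2.712,0.296,0.35,7.92,0.12
1,9,6.140,0.301,-0.41,-7.88,0.33
2,5,4.439,0.280,7.90,0.55,-0.21
3,2,2.700,0.310,5.61,5.60,0.05
3,2,6.120,0.312,5.58,5.64,0.11
4,11,6.128,0.290,0.02,5.66,5.70
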