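# Reference per-subject summary measures: one control (Con1) and two Chiari I
# patients (P1, P2). Velocities mm/s, pressures Pa, resistances g/(mm^4 s),
# station heights mm, cycle timings in percent of cycle.
subject,heart_rate_bpm,umax_CS_mms,umax_Aq_mms,umax_FM_mms,dp_PC_CS_max_Pa,dp_PC_CS_min_Pa,dp_Aq_PC_max_Pa,dp_Aq_PC_min_Pa,dp_PC_CS_tQmax_Pa,z_CS_mm,z_PC_mm,z_Aq_mm,R_PC_CS_sys,R_PC_CS_dia,R_Aq_PC_sys,R_Aq_PC_dia,theta,caudal_pct,peak_systole_pct,aq_delay_pct
Con1,71,59,134,27,33.6,-17.4,13.1,-14.4,2.8,35,110,128,0.008,0.006,0.072,0.072,0.27,26,8,28
P1,86,43,38,123,44.4,-14.6,1.4,-1.5,4.4,35,110,135,0.018,0.006,0.022,0.022,0.36,47,17.5,15
P2,77,98,116,439,83.9,-39.6,8.2,-6.4,53.6,35,110,135,0.023,0.017,0.020,0.020,0.31,37,14,16
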