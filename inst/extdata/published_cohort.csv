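quantity,value
n_patients,192
n_recurrent,33
n_nonrecurrent,159
gleason_5_6,67
gleason_3p4,89
gleason_4p3,14
gleason_8_10,22
epe_positive,3
svi_positive,14
sm_positive,33
psa_median,5.6
followup_mean_months,59
gleason_5_6_recurrence_pct,2.98
gleason_3p4_recurrence_pct,12.35
gleason_4p3_recurrence_pct,42.85
gleason_8_10_recurrence_pct,63.63
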