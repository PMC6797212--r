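name,value
GMAX_PD_ES.Kp,-3.439104935
GMAX_PD_ES.Kv,1.470787333
GMAX_PD_ES.theta_o,-0.2064248062
GMAX_PD_MS.Kp,1.179250648
GMAX_PD_MS.Kv,-0.4885348421
GMAX_PD_MS.theta_o,0.07450834215
GMAX_PD_PS.Kp,7.309995113
GMAX_PD_PS.Kv,-1.229628854
GMAX_PD_PS.theta_o,-0.1781358519
GMAX_C_S.K,0.7477939103
GMAX_F_ES.K,0.3878157811
ILPSO_PD_ES.Kp,3.007936879
ILPSO_PD_ES.Kv,1.072155806
ILPSO_PD_ES.theta_o,-0.3033899185
ILPSO_PD_MS.Kp,-3.016648965
ILPSO_PD_MS.Kv,-0.3007925774
ILPSO_PD_MS.theta_o,-0.2814658386
ILPSO_PD_PS.Kp,-1.620152121
ILPSO_PD_PS.Kv,-0.4607090902
ILPSO_PD_PS.theta_o,-0.08068171562
ILPSO_L_S.K,1.12692521
ILPSO_L_S.l_o,0.9572676971
ILPSO_C_S.K,0.9119582829
HAMS_PD_ES.Kp,0.304839894
HAMS_PD_ES.Kv,1.31532306
HAMS_PD_ES.theta_o,-0.09174383169
HAMS_PD_MS.Kp,-3.185315856
HAMS_PD_MS.Kv,-1.112593003
HAMS_PD_MS.theta_o,0.2951631185
HAMS_PD_PS.Kp,2.643245483
HAMS_PD_PS.Kv,1.440032718
HAMS_PD_PS.theta_o,-0.0295266129
HAMS_L_LP.K,1.533862329
HAMS_L_LP.l_o,1.44403779
HAMS_F_PS.K,1.845679042
RF_F_ES.K,0.3807538306
RF_F_MS.K,1.818120959
RF_C_S.K,0.2908055525
RF_V_LP.K,2.043852273
VAS_F_ES.K,0.3425512417
VAS_F_MS.K,1.002781325
VAS_F_PS.K,2.306067172
VAS_C_LP.K,0.2432876033
VAS_L_ES.K,1.123783813
VAS_L_ES.l_o,1.358333525
VAS_F_LP.K,1.80472115
BFSH_L_S.K,2.446232549
BFSH_L_S.l_o,0.6822995816
BFSH_V_S.K,2.858151387
BFSH_C_PS.K,0.595860021
GAS_F_ES.K,1.344748762
GAS_F_MS.K,3.838536405
GAS_F_PS.K,2.295678154
GAS_C_S.K,0.6213114271
GAS_L_PS.K,4.338768521
GAS_L_PS.l_o,1.111872508
SOL_F_ES.K,0.4715289067
SOL_F_MS.K,0.8438166923
SOL_F_PS.K,1.36066479
SOL_L_ST.K,2.324182266
SOL_L_ST.l_o,0.6051407396
SOL_C_PS.K,0.0947649662
TA_L_STANCE.K,1.193298383
TA_L_STANCE.l_o,0.5439513424
TA_L_SWING.K,2.37565014
TA_L_SWING.l_o,1.561689674
TA_FSOL_ES.K,1.286813961
TA_FSOL_MS.K,0.6729331869
TA_FSOL_PS.K,2.014675789
TA_C_S.K,0.4896489582
es_to_ms_dist_m,-0.3211695621
ps_to_s_grf_N,214.8563043
s_to_lp_dist_m,0.08822165978
lp_to_es_grf_N,148.6993234
pelvis_tilt_rad,0.3255386145
hip_L_rad,0.7324367987
knee_L_rad,0.03947427223
ankle_L_rad,-0.5661350068
hip_R_rad,0.4495753399
knee_R_rad,1.493177098
ankle_R_rad,0.2475613988
pelvis_vx_m_s,0.8796891198
pelvis_vy_m_s,0.6055211178
pelvis_tilt_vel_rad_s,-0.8346492441
hip_L_vel_rad_s,-2.457037241
knee_L_vel_rad_s,0.6669583195
ankle_L_vel_rad_s,2.877006961
hip_R_vel_rad_s,2.785769922
knee_R_vel_rad_s,1.922388883
ankle_R_vel_rad_s,0.08384181283
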