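# Default planar 9-DOF walking model: an adult of ~1.80 m and 75.16 kg.
#
# Inertial and muscle parameters are literature-informed approximations for a
# planar lower-limb model with lumped sagittal muscle groups; they are meant
# to be edited.  Units are encoded in field names.  Angle conventions:
# flexion positive at hip and knee, dorsiflexion positive at the ankle,
# anterior pelvis tilt positive; ground plane at y = 0.
#
# Muscle path model: MTU length = L0 + sum_j [c1*theta_j + c2*theta_j^2]
# over spanned joints, with L0 = l_opt + l_tendon_slack at the reference pose
# (all joint angles zero).  Moment arm about joint j is -(c1 + 2*c2*theta_j)
# (tendon-excursion identity), so a positive c1 means the muscle lengthens
# with positive joint rotation (an extensor at hip/knee, a plantarflexor at
# the ankle under the conventions above).
name: planar-adult-9dof
gravity_m_s2: 9.80665
fall_com_fraction: 0.8
segments:
  trunk:   # pelvis + torso + head + arms, lumbar welded at 5 deg flexion
    mass_kg: 50.76
    inertia_kgm2: 2.60
    length_m: 0.60
    com_offset_m: 0.32
  thigh:
    mass_kg: 7.50
    inertia_kgm2: 0.130
    length_m: 0.44
    com_offset_m: 0.19
  shank:
    mass_kg: 3.50
    inertia_kgm2: 0.055
    length_m: 0.43
    com_offset_m: 0.19
  foot:
    mass_kg: 1.20
    inertia_kgm2: 0.010
    length_m: 0.26
    com_offset_x_m: 0.05
    com_offset_y_m: -0.04
head_point_height_m: 0.70   # head point on the trunk, above the pelvis origin
joints:
  pelvis_ground: {kind: planar-3dof}
  lumbar:        {kind: locked, locked_angle_deg: 5}
  hip:           {kind: pin-1dof, range_limit_deg: [-30, 120]}
  knee:          {kind: coupled-knee-1dof, range_limit_deg: [0, 140],
                  # tibiofemoral translation polynomial in knee angle;
                  # the shipped default is the pure-pin (zero) polynomial
                  translation_poly_m: [0.0, 0.0, 0.0]}
  ankle:         {kind: pin-1dof, range_limit_deg: [-40, 20]}
ligaments:
  stiffness_Nm: 6.0     # exponential limit-spring scale
  width_deg: 3.0        # e-folding width beyond the engagement limit
contact:
  plane_strain_modulus_N_m2: 500000
  dissipation_s_m: 1.0
  mu_static: 0.8
  mu_dynamic: 0.8
  mu_viscous: 0.0
  transition_velocity_m_s: 0.1
  spheres:              # local offsets in the foot frame (origin at ankle)
    heel:        {radius_m: 0.050, offset_x_m: -0.05, offset_y_m: -0.020}
    toe_medial:  {radius_m: 0.025, offset_x_m:  0.09, offset_y_m: -0.045}
    toe_lateral: {radius_m: 0.025, offset_x_m:  0.15, offset_y_m: -0.045}
curves:
  active_fl_width: 0.45          # active force-length: exp(ln(0.05)*|(l-1)/w|^3)
  passive_kpe: 4.0               # passive force-length exponential shape
  passive_strain_at_one: 0.6     # passive strain at which multiplier = 1
  tendon_shape_k: 3.0            # tendon toe-region exponential shape
  fv_curvature_K: 0.25           # Hill hyperbola curvature (concentric)
  fv_eccentric_plateau_N: 1.5    # eccentric force plateau multiplier
metabolics:
  specific_tension_N_m2: 250000  # for muscle mass = Fmax/sigma * rho * lopt
  muscle_density_kg_m3: 1059.7
  basal_rate_W_kg: 1.2           # whole-body basal rate added in the objective
muscles:
  # 9 sagittal muscle groups per leg; bilateral mirror is implied.
  # tendon_strain_at_fmax is 0.049 except the plantarflexors (0.10).
  GMAX:
    f_max_iso_N: 2500
    l_opt_m: 0.160
    l_tendon_slack_m: 0.110
    tendon_strain_at_fmax: 0.049
    v_max_lopt_s: 15
    tau_act_s: 0.010
    tau_deact_s: 0.040
    passive_curve_scale: 1.0
    fast_twitch_fraction: 0.45
    path: {hip: {c1_m_rad: 0.062, c2_m_rad2: 0.0}}
  HAMS:
    f_max_iso_N: 3000
    l_opt_m: 0.110
    l_tendon_slack_m: 0.330
    tendon_strain_at_fmax: 0.049
    v_max_lopt_s: 15
    tau_act_s: 0.010
    tau_deact_s: 0.040
    passive_curve_scale: 0.5    # reduced passive curve (biarticular hamstrings)
    fast_twitch_fraction: 0.40
    path: {hip: {c1_m_rad: 0.060, c2_m_rad2: 0.0},
           knee: {c1_m_rad: -0.030, c2_m_rad2: 0.0}}
  ILPSO:
    f_max_iso_N: 2100
    l_opt_m: 0.110
    l_tendon_slack_m: 0.140
    tendon_strain_at_fmax: 0.049
    v_max_lopt_s: 15
    tau_act_s: 0.010
    tau_deact_s: 0.040
    passive_curve_scale: 1.0
    fast_twitch_fraction: 0.50
    path: {hip: {c1_m_rad: -0.045, c2_m_rad2: 0.0}}
  RF:
    f_max_iso_N: 1200
    l_opt_m: 0.084
    l_tendon_slack_m: 0.300
    tendon_strain_at_fmax: 0.049
    v_max_lopt_s: 15
    tau_act_s: 0.010
    tau_deact_s: 0.040
    passive_curve_scale: 0.5    # reduced passive curve (rectus femoris)
    fast_twitch_fraction: 0.55
    path: {hip: {c1_m_rad: -0.035, c2_m_rad2: 0.0},
           knee: {c1_m_rad: 0.045, c2_m_rad2: 0.0}}
  VAS:
    f_max_iso_N: 6000
    l_opt_m: 0.089
    l_tendon_slack_m: 0.220
    tendon_strain_at_fmax: 0.049
    v_max_lopt_s: 15
    tau_act_s: 0.010
    tau_deact_s: 0.040
    passive_curve_scale: 0.5    # reduced passive curve (vasti)
    fast_twitch_fraction: 0.50
    path: {knee: {c1_m_rad: 0.045, c2_m_rad2: 0.0}}
  BFSH:
    f_max_iso_N: 800
    l_opt_m: 0.120
    l_tendon_slack_m: 0.100
    tendon_strain_at_fmax: 0.049
    v_max_lopt_s: 15
    tau_act_s: 0.010
    tau_deact_s: 0.040
    passive_curve_scale: 1.0
    fast_twitch_fraction: 0.50
    path: {knee: {c1_m_rad: -0.030, c2_m_rad2: 0.0}}
  GAS:
    f_max_iso_N: 2500
    l_opt_m: 0.055
    l_tendon_slack_m: 0.400
    tendon_strain_at_fmax: 0.10   # plantarflexor: compliant tendon
    v_max_lopt_s: 15
    tau_act_s: 0.010
    tau_deact_s: 0.040
    passive_curve_scale: 1.0
    fast_twitch_fraction: 0.50
    path: {knee: {c1_m_rad: -0.020, c2_m_rad2: 0.0},
           ankle: {c1_m_rad: 0.050, c2_m_rad2: 0.0}}
  SOL:
    f_max_iso_N: 4250             # ~70% stronger than GAS
    l_opt_m: 0.050
    l_tendon_slack_m: 0.250
    tendon_strain_at_fmax: 0.10   # plantarflexor: compliant tendon
    v_max_lopt_s: 15
    tau_act_s: 0.010
    tau_deact_s: 0.040
    passive_curve_scale: 1.0
    fast_twitch_fraction: 0.20
    path: {ankle: {c1_m_rad: 0.050, c2_m_rad2: 0.0}}
  TA:
    f_max_iso_N: 1000
    l_opt_m: 0.098
    l_tendon_slack_m: 0.200
    tendon_strain_at_fmax: 0.049
    v_max_lopt_s: 15
    tau_act_s: 0.010
    tau_deact_s: 0.040
    passive_curve_scale: 1.0
    fast_twitch_fraction: 0.30
    path: {ankle: {c1_m_rad: -0.040, c2_m_rad2: 0.0}}
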