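segment,proximal_kp,distal_kp,mass_frac,com_ratio
head,nose,neck,0.0694,0.5002
trunk,neck,mid_hip,0.4346,0.4486
upper_arm_r,r_shoulder,r_elbow,0.0271,0.5772
upper_arm_l,l_shoulder,l_elbow,0.0271,0.5772
forearm_r,r_elbow,r_wrist,0.0223,0.6751
forearm_l,l_elbow,l_wrist,0.0223,0.6751
upper_leg_r,r_hip,r_knee,0.1416,0.4095
upper_leg_l,l_hip,l_knee,0.1416,0.4095
lower_leg_r,r_knee,r_ankle,0.0433,0.4459
lower_leg_l,l_knee,l_ankle,0.0433,0.4459
foot_r,r_ankle,r_big_toe,0.0137,0.4415
foot_l,l_ankle,l_big_toe,0.0137,0.4415
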