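# Body segment inertial parameters for the 12-segment walking model
# (trunk/thorax, pelvis, and paretic/non-paretic upper arms, forearms,
# thighs, shanks, feet; head and hands excluded).
# Approximate adult-male values after the Dumas et al. (2007) adjusted
# anthropometric compilation; supply your own table for other populations.
# mass_fraction: segment mass / body mass
# length_fraction: segment length / stature
# com_ratio: CoM position along the proximal->distal axis, 0 = proximal
# rgyr_frontal: radius of gyration about the frontal (anterior-posterior)
#   axis, as a fraction of segment length
segment,mass_fraction,length_fraction,com_ratio,rgyr_frontal
trunk,0.304,0.300,0.45,0.33
pelvis,0.142,0.100,0.50,0.60
p_upperarm,0.024,0.186,0.45,0.31
n_upperarm,0.024,0.186,0.45,0.31
p_forearm,0.017,0.146,0.43,0.28
n_forearm,0.017,0.146,0.43,0.28
p_thigh,0.123,0.245,0.42,0.32
n_thigh,0.123,0.245,0.42,0.32
p_shank,0.048,0.246,0.40,0.28
n_shank,0.048,0.246,0.40,0.28
p_foot,0.012,0.152,0.44,0.25
n_foot,0.012,0.152,0.44,0.25
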