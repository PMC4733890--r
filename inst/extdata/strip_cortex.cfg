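# Default synthetic geography: five parallel strips with alternating
# visual field sign, emulating the V2 -> DLp -> DLi -> DLa -> MT corridor.
# Eccentricity runs 2-50 deg along x (12 mm); polar angle sweeps -80..+80 deg
# across each 2 mm strip, reversing direction at every border.
n_strips 5
names V2,DLp,DLi,DLa,MT
width 12
strip_height 2
r_min 2
r_max 50
theta_min -80
theta_max 80
scatter_sd 0
rf_a 2
rf_b 0.15
seed 1
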