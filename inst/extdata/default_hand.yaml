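# Packaged parametric hand geometry: a generic ~19 cm adult hand,
# 21 bone segments, 21 actuated joint axes, 65 skin spheres.
kind: parametric_hand
hand_scale: 1.0
joint_limits: true
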