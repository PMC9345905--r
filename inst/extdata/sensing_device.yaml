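# Two-plate fingertip force-sensing device (grasp target fixture).
# Two parallel 20 mm x 49 mm aluminium plates (long axis vertical) on
# opposite sides of the housing; plate separation and friction are
# configurable, the mass is the device's 198.4 g.
kind: sensing_device
mass_g: 198.4
plate_mm: [20.0, 49.0]
separation_mm: 40.0
mu_actual: 0.8
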