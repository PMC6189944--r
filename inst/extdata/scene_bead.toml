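# 100-um polystyrene bead with high-density image noise kept clear of
# the circular ROI (a = b = 20 px) engaged after stable tracking.
background = 200
target.kind = bead
target.radius_um = 50
target.intensity = 20
noise.n = 15
noise.radius_px = [5, 25]
noise.keepout_px = 22
noise.start_t = 0.3
start_pos_um = [15000, 15000]
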