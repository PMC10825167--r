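# Standard human red/green tagging session: fixed red at 21.04 cd/m^2,
# ten green levels spanning the physical match, 1.77 Hz tagging.
fixed_colour: red
fixed_luminance: 21.04
variable_colour: green
variable_levels: [4.58, 8.65, 12.73, 16.80, 20.87, 24.95, 29.02, 33.09, 37.17, 41.24]
half_period_s: 0.283
refresh_hz: 120
frames_per_half_period: 34
repeats: 5
trial_duration_s: 3.5
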