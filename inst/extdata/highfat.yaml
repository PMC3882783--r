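# High-fat (obese) cohort phantom: parameters transcribed from the printed
# group means; the septal-to-lateral activation delay amplitude is calibrated
# so the analytic radial uniformity index (RURE) is about 0.91.
endo_radius_ed: 1.38
epi_radius_ed: 2.36
long_axis_length_ed: 10.0
apex_wall_thickness: 1.0
circ_stretch_endo: 0.85     # -15%
circ_stretch_epi: 0.933     # -6.7%
long_stretch: 0.894         # about -10.6%
twist_base_peak: 0.0
twist_apex_peak: 6.6        # degrees at the apical slice (6.6 deg/cm over 1 cm)
delay_amplitude_ms: 33.05   # calibrated so analytic RURE = 0.91
septum_angle_deg: 180
heart_rate: 503
systole_ms: 49.7
ke: 1.0
field_of_view: 32
matrix_size: 128
tr: 7.1
phase_noise_sd: 0.0
random_seed: 2
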