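# Low-fat (control) cohort phantom: parameters transcribed from the printed
# group means (peak layer strains, torsion over a 1.0 cm long axis, heart
# rate, end-diastolic volume and mass).
endo_radius_ed: 1.41        # mm, mid-ventricular, end-diastole
epi_radius_ed: 2.26         # mm
long_axis_length_ed: 10.0   # mm (epicardial)
apex_wall_thickness: 1.0    # mm
circ_stretch_endo: 0.83     # peak subendocardial circumferential stretch (-17%)
circ_stretch_epi: 0.906     # peak subepicardial circumferential stretch (-9.4%)
long_stretch: 0.88          # peak longitudinal stretch (-12%)
twist_base_peak: 0.0        # degrees at the basal slice
twist_apex_peak: 8.8        # degrees at the apical slice
delay_amplitude_ms: 0.0     # synchronous contraction
septum_angle_deg: 180
heart_rate: 457             # bpm
systole_ms: 49.7            # onset-to-peak interval
ke: 1.0                     # cycles/mm
field_of_view: 32           # mm
matrix_size: 128
tr: 7.1                     # ms
phase_noise_sd: 0.0
random_seed: 1
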