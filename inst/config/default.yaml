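# Default end-to-end study profile.
# Every field is optional; omitted fields keep the package defaults shown
# here. Load with read_pipeline_config() and execute with run_pipeline().

filter_threshold: 0.9      # redundancy filter on |Spearman rho|
alpha: 0.05                # significance level on FDR-adjusted q
resolutions: [50, 100, 150, 200]   # cell-density map tile sizes, um
seed: 1

simulate:
  n_patients: 48
  n_latent: 3
  coupling: 0.6            # 0 = null cohort (no cross-scale association)
  noise_sd: 0.3
  slides_per_patient: [1, 3]
  volume_shape: [32, 32, 16]
  voxel_spacing: [1, 1, 2] # mm
  roi_size_um: [1000, 1000]
  nuclei_intensity: 1200   # expected nuclei per mm^2
  seed: 1

adc_config:
  discretization: width
  bin_width: 25            # ADC map units (1e-6 mm^2/s)
t1c_config:
  discretization: width
  bin_width: 0.1           # T1C is z-normalized first (unit scale)
density_config:
  discretization: count
  bin_count: 32
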