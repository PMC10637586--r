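# Minimal end-to-end configuration: a small synthetic cohort, reduced
# consensus sampling and the unfiltered core feature set. Merged over the
# package defaults by read_config().
seed: 7
input:
  synthetic:
    cohort:
      n_train: 12
      n_test: 6
      seed: 3
    phantom:
      grid_shape: [24, 24, 8]
      tumour_axes: [9, 9, 9]
habitat:
  k_range: [2, 3, 4, 5]
  reps: 50
  max_items: 600
  max_voxels_per_patient: 200
radiomics:
  families: [firstorder, glcm, shape]
  filters: [original]
selection:
  icc_n: 5
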