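# Demo pipeline configuration: one activated platelet (10 min stage) with
# three 410 nm clusters, simulated frames, localization, segmentation,
# radial and directionality analysis. Any field omitted here keeps the
# package default (see plateletquant::default_config()).
seed: 1
outdir: plateletquant-demo-out
stages:
  - stage_min: 10
    n_platelets: 1
scene:
  platelet_radius_nm: 1500
  n_clusters: 3
  cluster_diameter_nm: 410
  locs_per_cluster: 80
  precision_nm: 20
localize:
  enabled: true
  n_frames: 600
  blink_on_prob: 0.02
  photons_mean: 1000
  psf_sigma_nm: 120
  camera_pixel_nm: 100
  background_rate: 10
render:
  pixel_size_nm: 20
  mode: gaussian
  gaussian_sd_nm: 20
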