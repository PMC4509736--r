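# TIRF demo: stationary dye molecules on a coverslip, EMCCD detection.
modality: tirfm
seed: 1
sample:
  model: plate
  "n": 100
  fov_x_um: 39.9
  fov_y_um: 41.0
  n_frames: 3
  dt_s: 0.03
  species: HaloTag-TMR
psf:
  na: 1.49
  "n": 1.52
  r_max_um: 1.5
  z_max_um: 1.5
  dr_um: 0.01
  dz_um: 0.01
  Lambda_um: 1.0
detector:
  nx: 152
  ny: 156
  pixel_size_um: 16
  magnification: 60
  focal_plane_um: 0
tirf:
  phi_W_per_cm2: 20
  lambda_nm: 532
  theta_deg: 70
  n1: 1.52
  n2: 1.33
  polarization: s
camera:
  qe: 0.92
  readout_noise: 100
  dark_current: 0.005
  em_gain: 300
  conversion_gain: 5.8
  offset: 2000
  bit_depth: 16
  binning: 1
  exposure_s: 0.03
output:
  dir: tirfm_out
  prefix: plate
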