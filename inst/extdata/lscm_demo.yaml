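# LSCM demo: diffusing dye solution imaged at mid-depth, photon-counting PMT.
# The molecule count is a down-scaled stand-in for the full 19,656-molecule
# solution benchmark; raise sample.n to reproduce it.
modality: lscm
seed: 1
sample:
  model: box
  "n": 1000
  Lx_um: 30
  Ly_um: 30
  Lz_um: 6
  D_um2_per_s: 100
  dt_s: 1.0e-3
  n_frames: 2
  species: HaloTag-TMR
psf:
  na: 1.49
  "n": 1.52
  r_max_um: 1.5
  z_max_um: 3.0
  dr_um: 0.01
  dz_um: 0.02
  Lambda_um: 1.0
detector:
  nx: 100
  ny: 100
  pixel_size_um: 31.1
  magnification: 60
  focal_plane_um: 3.0
lscm:
  Phi_W: 5.0e-6
  lambda_nm: 488
  w0_um: 0.25
  "n": 1.33
  R_um: 28.8
  dwell_s: 1.0e-4
pmt:
  qe: 0.30
  dark_count_rate: 50
  gain: 1
  conversion_gain: 1
  offset: 0
  bit_depth: 12
output:
  dir: lscm_out
  prefix: solution
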