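# example run configuration for the dlao command-line interface
optics:
  wavelength: 690
  na: 1.35
  n_immersion: 1.406
  n_sample: 1.35
  pixel_size: 119
  pupil_grid: 64
  psf_size: 32
acquisition:
  frame_size: 128
  mean_emitters: 13
  mean_photons: 2500
  background: 10
  frames_per_cycle: 20
  photon_threshold: 1500
loop:
  max_updates: 20
  gain: 1.0
seed: 1
output_dir: dlao-out
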