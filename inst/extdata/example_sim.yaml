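# Synthetic retinal pulse video: a horizontal vein crossing a ~1 mm field,
# pulsing at a true PWV of 22 mm/s with SNR 5 (see simulation_config()).
width: 48
height: 32
fps: 120
frames_per_cycle: [102, 102, 103]
cycle_time_s: 0.852743
vessel_path:
  - [16, 4]
  - [16, 44]
vessel_radius_px: 1.2
baseline: 120
amplitude: 8
pwv_true_mm_s: 22
mm_per_pixel: 0.02
drift: [3, -5, 4]
rho_true: 0.3
snr: 5
seed: 7
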