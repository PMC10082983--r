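# Cardiac timing for a three-cycle, 307-frame recording at 120 FPS:
# cycle boundaries are 0-based frame indices derived from the pulse-oximetry
# audio track; the last entry is one past the final analyzed frame.
fps: 120
cycle_boundaries: [0, 102, 204, 307]
cycle_time_s: 0.852743
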