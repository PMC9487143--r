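# Example tagscope acquisition configuration.
#
# A 512 x 512 bidirectional 2D acquisition driven by a resonant scanner
# (15.36 kHz line rate -> 30 frames/s), one green spectral channel and the
# line synchronization signal.  Negative input numbers trigger on the
# falling edge of the signal.

rows = 512
columns = 512
planes = 1                    # 1 = 2D; volumetric needs an even count > 1
bidirectional = true
fill_fraction = 0.8           # visible share of each line period
line_frequency_hz = 15360     # 2 x 7.68 kHz mirror, bidirectional
laser_period_ps = 12_500      # 80 MHz pulsed source
demultiplex = false
bidir_phase_ps = 0            # odd-line window shift (line-shift correction)
rolling_window_frames = 30    # display sum over the last 30 frames
filename = "run001"
replay_existing = false

[[channels]]
input_number = 1
role = "line_sync"
threshold = 0.5
label = "scanner line sync"

[[channels]]
input_number = -2
role = "spectral"
threshold = -0.25
label = "green PMT (falling edge)"
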