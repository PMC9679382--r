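# Example pipeline configuration for the mms-gamma command line.
# Fields omitted here keep the package defaults.

# cohort composition (simulate)
nBroad: 10
nNarrow: 13
nCorrelated: 23
nRandom: 24
blockS: 300          # seconds per block
nChannels: 32
rate: 256            # Hz

# analysis parameters
windowS: 5           # sliding window (s)
overlap: 0.5         # window overlap fraction
band: [13, 100]      # Hz
order: 20            # bandpass order
bins: 20             # histogram bins on [0, 1]
minPeaks: 100        # minimum spikes per accepted window

masterSeed: 1
nBoot: 5000          # dip-test bootstrap replicates
format: edf          # recording format written by simulate
outDir: mmsgamma-out
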