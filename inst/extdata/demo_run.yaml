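# Demonstration pipeline configuration: a small synthetic cohort that runs
# end to end in a few minutes on one CPU.
mode: synthetic
seed: 42
cohort:
  n_bd: 6
  n_hc: 6
  duration: 36        # seconds per paradigm (6 epochs)
paradigms:
  - eyes_closed
  - eyes_open
q: 0.05
welch: false
cv:
  k: 3
  repeats: 2
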