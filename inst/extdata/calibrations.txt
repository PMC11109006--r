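[mouse-IL-5]
time_unit: min
decay_taus: 34000
decay_weights: 1
assoc_taus: 7.5999999999999996 84
assoc_weights: 0.59899999999999998 0.40100000000000002

[human-IL-5]
time_unit: h
decay_taus: 280
decay_weights: 1
assoc_taus: 0.27000000000000002
assoc_weights: 1

[human-IL-13]
time_unit: h
decay_taus: 0.83999999999999997 210
decay_weights: 0.70999999999999996 0.29000000000000004
assoc_taus: 1
assoc_weights: 1

[crosstalk-13to5]
time_unit: h
decay_taus: 280
decay_weights: 1
assoc_taus: 0.23000000000000001 25
assoc_weights: 0.23000000000000001 0.77000000000000002
beta: 0.33000000000000002

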