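# etongue-params v1
# Inverse prediction-model constants reported for a laboratory
# calibration of the sweetness/saltiness sensor pair on the 16-sample
# acesulfame K (0, 0.25, 0.5, 1 mM) x NaCl (0, 10, 30, 50 mM) design.
a = -50.75  # mV
b = -47.6  # mV
j = 0.50  # mM
k = -0.49  # mM
m = -177.45  # mM
n = 176.35  # mM
c = -0.024  # mM
d = 114.51  # mM
e = -16.92  # mV
f = -54.35  # mV
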