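# Default configuration of the UCSD-style weighted-window actigraphy
# scorer. The algorithm rates each successive minute as wake or sleep
# from a 7-minute span of per-minute activity: the current minute, the
# 4 preceding and the 2 subsequent minutes. The published design fixes
# the span; the coefficient values below are package defaults in the
# classic weighted-window family and should be overridden with the
# validated coefficients for a specific device/count mode.
version: 1
count_mode: PIM
# weights for minutes t-4, t-3, t-2, t-1, t, t+1, t+2
weights: [0.00404, 0.00598, 0.00326, 0.00441, 0.01408, 0.00508, 0.00350]
# weighted sum below this bound scores the minute as sleep
threshold: 1.0
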