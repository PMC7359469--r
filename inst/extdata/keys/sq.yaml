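# Systemizing Quotient scoring key (editable default).
# 60 items on a 4-point agreement scale; 40 scored items yield 2/1/0
# points toward the systemizing side, 20 fillers yield nothing.
# Single total scale, range 0-80.
instrument: sq
label: Systemizing Quotient
n_items: 60
scale_min: 1
scale_max: 4
points_scheme: agree2
subscales:
  sq: [1, 4, 5, 6, 7, 11, 12, 13, 15, 18, 19, 21, 23, 24, 25, 26, 28, 29, 30, 31, 32, 33, 34, 35, 37, 38, 40, 41, 42, 43, 44, 45, 48, 49, 51, 53, 55, 56, 57, 58]
reverse: [6, 11, 12, 18, 21, 26, 28, 31, 32, 35, 38, 40, 42, 43, 45, 51, 55, 56, 57, 58]
filler: [2, 3, 8, 9, 10, 14, 16, 17, 20, 22, 27, 36, 39, 46, 47, 50, 52, 54, 59, 60]
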