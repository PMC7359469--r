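# Empathy Quotient scoring key (editable default).
# 60 items on a 4-point agreement scale; 40 scored items yield 2/1/0 points
# toward the empathic side, 20 fillers yield nothing. Factor membership
# follows the validated three-factor solution: cognitive empathy (ce, 11),
# emotional reactivity (er, 11), social skills (ss, 6); the remaining 12
# scored items (other) contribute to the total only.
# "reverse" lists the items keyed on the disagreement side.
instrument: eq
label: Empathy Quotient
n_items: 60
scale_min: 1
scale_max: 4
points_scheme: agree2
subscales:
  ce: [1, 25, 26, 36, 41, 43, 44, 52, 54, 55, 58]
  er: [6, 21, 22, 27, 29, 32, 42, 48, 49, 50, 59]
  ss: [4, 8, 12, 14, 35, 57]
  other: [10, 11, 15, 18, 19, 28, 34, 37, 38, 39, 46, 60]
reverse: [4, 8, 10, 11, 12, 14, 15, 18, 21, 27, 28, 29, 32, 34, 39, 46, 48, 49, 50]
filler: [2, 3, 5, 7, 9, 13, 16, 17, 20, 23, 24, 30, 31, 33, 40, 45, 47, 51, 53, 56]
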