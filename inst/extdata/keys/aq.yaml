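# Autism-Spectrum Quotient scoring key (editable default).
# 50 items on a 4-point scale scored binary: 1 point for any response on
# the autism-keyed side (agree for the items below, disagree for the
# reverse-listed items). Five 10-item domains; total range 0-50,
# clinical cut-off 32.
instrument: aq
label: Autism-Spectrum Quotient
n_items: 50
scale_min: 1
scale_max: 4
points_scheme: agree1
subscales:
  social_skill:        [1, 11, 13, 15, 22, 36, 44, 45, 47, 48]
  attention_switching: [2, 4, 10, 16, 25, 32, 34, 37, 43, 46]
  attention_to_detail: [5, 6, 9, 12, 19, 23, 28, 29, 30, 49]
  communication:       [7, 17, 18, 26, 27, 31, 33, 35, 38, 39]
  imagination:         [3, 8, 14, 20, 21, 24, 40, 41, 42, 50]
reverse: [1, 3, 8, 10, 11, 14, 15, 17, 24, 25, 27, 28, 29, 30, 31, 32, 34, 36, 37, 38, 40, 44, 47, 48, 49, 50]
filler: []
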