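# Interpersonal Reactivity Index scoring key (editable default).
# 28 items, 1-5 response scale, four 7-item subscales; points equal the
# response, reverse-keyed items mirrored (points = 6 - response).
instrument: iri
label: Interpersonal Reactivity Index
n_items: 28
scale_min: 1
scale_max: 5
points_scheme: identity
subscales:
  pt: [3, 8, 11, 15, 21, 25, 28]   # perspective taking
  fs: [1, 5, 7, 12, 16, 23, 26]    # fantasy
  ec: [2, 4, 9, 14, 18, 20, 22]    # empathic concern
  pd: [6, 10, 13, 17, 19, 24, 27]  # personal distress
reverse: [3, 4, 7, 12, 13, 14, 15, 18, 19]
filler: []
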