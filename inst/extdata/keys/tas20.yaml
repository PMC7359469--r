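# Toronto Alexithymia Scale (TAS-20) scoring key (editable default).
# 20 items on 1-5; points equal the response with five reverse-keyed items.
# Subscales: difficulty identifying feelings (dif, 7), difficulty
# describing feelings (ddf, 5), externally oriented thinking (eot, 8).
instrument: tas20
label: Toronto Alexithymia Scale
n_items: 20
scale_min: 1
scale_max: 5
points_scheme: identity
subscales:
  dif: [1, 3, 6, 7, 9, 13, 14]
  ddf: [2, 4, 11, 12, 17]
  eot: [5, 8, 10, 15, 16, 18, 19, 20]
reverse: [4, 5, 10, 18, 19]
filler: []
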