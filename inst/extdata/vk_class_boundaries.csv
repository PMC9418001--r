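# Van Krevelen compound-class rectangles (half-open: min <= x < max).
# Package default; follows the rectangular H/C x O/C conventions in common
# use for DOM classification. Rows must not overlap; unmatched points are
# classified "other". Edit a copy and pass it to vkClass(boundaries=...) to
# use a different convention.
class,hc_min,hc_max,oc_min,oc_max
condensed_aromatic,0.2,0.8,0.0,0.95
unsaturated_hydrocarbon,0.8,1.5,0.0,0.125
lignin,0.8,1.5,0.125,0.65
tannin,0.8,1.5,0.65,1.1
lipid,1.5,2.5,0.0,0.3
protein,1.5,2.3,0.3,0.55
amino_sugar,1.5,2.2,0.55,0.7
carbohydrate,1.5,2.5,0.7,1.5
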