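# Known limb-development genes used to annotate divergent-set
# intersections (editable; one symbol per line).
Tbx4
Tbx5
Pitx1
Hand1
Isl1
Myog
Pax1
Tnnt2
Grem1
Wnt5a
Fgf8
Shh
Hoxa13
Hoxd9
Hoxd11
Hoxd13
Evx2
Lnp
Med1
Ctnnb1
Fbn2
Prrx1
Prrx2
Rarb
Twist1
Col2a1
Mecom
Zbtb16
Msx1
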