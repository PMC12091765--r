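# thalidomide heavy-atom skeleton (hydrogen-depleted), 19 vertices, 21 edges
# phthalimide unit: benzene C1..C6 fused to the five-membered imide ring
C1 C2
C2 C3
C3 C4
C4 C5
C5 C6
C6 C1
C1 C7
C2 C8
C7 N9
C8 N9
C7 O7
C8 O8
# link to the glutarimide ring
N9 C10
C10 C11
C11 N12
N12 C13
C13 C14
C14 C15
C15 C10
C11 O11
C13 O13
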