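# hydroxy-chloroquine heavy-atom skeleton, 23 vertices, 24 edges
# chloroquine with one terminal ethyl oxidised to 2-hydroxyethyl
N1 C2
C2 C3
C3 C4
C4 C4a
C4a C5
C5 C6
C6 C7
C7 C8
C8 C8a
C8a N1
C4a C8a
C7 Cl
C4 N11
N11 C12
C12 C13
C12 C14
C14 C15
C15 C16
C16 N17
N17 C18
C18 C19
C19 O22
N17 C20
C20 C21
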