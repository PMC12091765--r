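# arbidol heavy-atom skeleton, 29 vertices, 31 edges
# indole core: pyrrole N1-C2-C3-C3a-C7a fused to benzene C3a..C7a
N1 C2
C2 C3
C3 C3a
C3a C7a
C7a N1
C3a C4
C4 C5
C5 C6
C6 C7
C7 C7a
# 1-methyl
N1 CM
# 2-(phenylthio)methyl
C2 CB1
CB1 S
S CP1
CP1 CP2
CP2 CP3
CP3 CP4
CP4 CP5
CP5 CP6
CP6 CP1
# 3-carbethoxy (ethyl ester)
C3 CE1
CE1 OE1
CE1 OE2
OE2 CE2
CE2 CE3
# 4-(dimethylamino)methyl
C4 CD1
CD1 ND
ND CD2
ND CD3
# 5-hydroxy, 6-bromo
C5 OH1
C6 Br
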