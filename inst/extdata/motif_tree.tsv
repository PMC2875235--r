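# Minimal control-region motif tree for the haplogroups observed in the El Jadida
# survey, distilled from the published mtDNA phylogenies for H, K, J/T/V/R, U, I/M1,
# X and L. Motif tokens use absolute rCRS positions (HVRI sites are NOT offset by
# -16000 here); a bare integer denotes a transition, integer+base a transversion.
# A node's effective motif is the union of its own tokens and all ancestors' tokens.
# This tree is a data fixture scoped to the haplogroups of this survey; it is not a
# full PhyloTree classifier and is user-replaceable.
name	parent	motif
mt-MRCA
H*	mt-MRCA	263
H1	H*	3010
H7	H*	4793
HV1	mt-MRCA	263 16067
V	mt-MRCA	72 263 16298
R0a	mt-MRCA	58 64 263 16126 16362
J	mt-MRCA	73 263 295 16069 16126
J2	J	150 152 16193
T	mt-MRCA	73 263 16126 16294
T1	T	16163 16186 16189
U	mt-MRCA	73 263 7028
U4	U	16356
U5b	U	16189 16270
U6a	U	16172 16219 16278
K	mt-MRCA	73 263 16224 16311
X	mt-MRCA	73 153 225 226 263 16189 16223 16278
N1b	mt-MRCA	73 204 263 16145 16176G 16223
M1	mt-MRCA	73 263 16129 16189 16249 16311
M1a	M1	16359
L1	mt-MRCA	73 263 16187 16189 16223 16278 16311
L1b1	L1	152 182 195 247 357 16126 16264 16270 16293
L1c4	L1	89 93 151 182 247 316 16293 16294 16360
L2	mt-MRCA	73 263 16278
L2a1	L2	143 146 152 195 16223 16294 16309 16390
L2c1	L2	16051 16172 16223 16266 16362
L2d1	L2	146 150 195 16129 16189 16300 16354 16357 16390
L3	mt-MRCA	73 263 16223
L3b1	L3	16124 16278 16362
L3d	L3	16124
L3d1'2'3'	L3d	16256
L3e2	L3	195 16320
L3e2a	L3e2	198
L3e2b	L3e2	150 236 316 16172 16189
L3f1	L3	189 200 16188 16295 16311
L3f1a	L3f1	152 235 16209
L3f1b	L3f1	16209
L3h1b	L3	151 152 195 294 16129 16256 16278 16311 16362
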