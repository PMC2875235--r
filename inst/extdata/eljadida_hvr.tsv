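# El Jadida (Morocco) mtDNA control-region survey: 81 individuals.
# HVRI positions are printed minus 16000 (restore by +16000); "0" = identical to rCRS.
# OTHER holds variants found in the four coding-region segments typed in candidate
# H/HV samples (3001-3360, 3661-4050, 4281-4820, 6761-7050); coding_typed = 1 marks
# samples for which those segments were sequenced (an empty OTHER then means no
# variant was found there).
sample_id	population	HVRI	HVRII	OTHER	haplogroup	coding_typed
J1	ElJadida	0	263 309.1 315.1		H*	1
J2	ElJadida	129 184	146 263 309.2 315.1		H*	1
J3	ElJadida	304	263 309.1 315.1		H*	1
J4	ElJadida	0	263 315.1	3010	H1	1
J5	ElJadida	0	263 309.1 315.1	3010	H1	1
J6	ElJadida	0	263 309.2 315.1	3010	H1	1
J7	ElJadida	0	263 309.1 315.1	3010	H1	1
J8	ElJadida	0	263 309.2 315.1	3010	H1	1
J9	ElJadida	209	114 146 263 309.1 315.1	3010	H1	1
J10	ElJadida	212	263 309.1 315.1	3010	H1	1
J11	ElJadida	218	263 309.2 315.1	3010	H1	1
J12	ElJadida	318A/C	114 263 309.2 315.1	3010	H1	1
J13	ElJadida	355	263 315.1	3010	H1	1
J14	ElJadida	0	263 309.1 315.1	4793	H7	1
J15	ElJadida	67	263 309.1 315.1		HV1	0
J16	ElJadida	93 298 311	72 263 315.1		V	0
J17	ElJadida	153 193 298	72 195 263 309.1 315.1		V	0
J18	ElJadida	153 298	72 195 263 315.1		V	0
J19	ElJadida	193	72 93 263 309.1 315.1		V	0
J20	ElJadida	298	72 195 263 309.1 315.1		V	0
J21	ElJadida	298	72 263 309.1 315.1		V	0
J22	ElJadida	298	72 263 309.1 315.1		V	0
J23	ElJadida	298	72 195 263 309.2 315.1		V	0
J24	ElJadida	126 291 362	58 64 152 263 315.1	7028	R0a	1
J25	ElJadida	126 291 362	58 64 152 263 315.1	7028	R0a	1
J26	ElJadida	126 362	58 64 263 315.1		R0a	0
J27	ElJadida	93 224 311	73 263 309.1 315.1		K	0
J28	ElJadida	224 287 311	73 146 263 309.1 315.1		K	0
J29	ElJadida	224 287 311	73 146 263 309.1 315.1		K	0
J30	ElJadida	224 287 311	73 146 263 309.1 315.1		K	0
J31	ElJadida	224 287 311	73 146 263 309.1 315.1		K	0
J32	ElJadida	224 287 311	73 146 263 309.1 315.1		K	0
J33	ElJadida	224 311	73 263 280G/C 315.1		K	0
J34	ElJadida	224 311	73 263 280C/G 315.1		K	0
J35	ElJadida	69 126	73 185 228 263 295 315.1		J	0
J36	ElJadida	69 126	73 185 225 228 263 295 315.1		J	0
J37	ElJadida	69 126 193 300 309	73 263 309.1 315.1		J	0
J38	ElJadida	69 126 193 265A/T	73 146 150 152 263 295 315.1		J2	0
J39	ElJadida	69 126 193 278 291	73 150 152 263 295 309.1 315.1		J2	0
J40	ElJadida	69 126 193 195 278	73 150 152 196insT 263 295 309.1 315.1		J2	0
J41	ElJadida	126 220 292 294	73 146 152 195 263 279 315.1		T	0
J42	ElJadida	126 163 186 189 193del 294	73 263 309.1 315.1		T1	0
J43	ElJadida	173 183A/C 189 223 278	73 146 153 195 225 226 263 309.1 315.1		X	0
J44	ElJadida	145 176C/G 223 311 390	73 152 204 263 315.1		N1b	0
J45	ElJadida	0	73 195 263 315.1	7028	U	1
J46	ElJadida	0	73 195 263 315.1	7028	U	1
J47	ElJadida	311	263 309.1 315.1	7028	U	1
J48	ElJadida	287 356	73 195 263 309.1 315.1		U4	0
J49	ElJadida	189 270	73 146 195 263 315.1		U5b	0
J50	ElJadida	172 189 219 261 278	73 263 309.1 315.1		U6a	0
J51	ElJadida	172 219 278 300	73 242 263 309.1 315.1		U6a	0
J52	ElJadida	129 183A/C 189 223 235 249 311	73 152 195 263 315.3		M1	0
J53	ElJadida	183A/C 189 249 265A/C 280 311	73 146 195 263 315.1		M1	0
J54	ElJadida	183A/C 189 249 265A/C 280 311	73 146 195 263 315.1		M1	0
J55	ElJadida	129 189 223 249 311 359	263 309.1 309.2 315.1		M1a	0
J56	ElJadida	129 189 223 249 311 359	73 195 198 263 315.1		M1a	0
J57	ElJadida	126 187 189 215A/T 223 264 270 278 293 311	73 152 182 185G/C 195 247 263 309.1 315.1 357		L1b1	0
J58	ElJadida	126 187 189 223 264 270 278 293 311	73 152 182 185G/T 189 195 207 247 263 309.1 315.1 357		L1b1	0
J59	ElJadida	126 187 189 223 264 270 278 293 311	73 152 182 185G/C 195 247 263 315.1 357		L1b1	0
J60	ElJadida	126 187 189 223 264 270 278 293 311 355	73 152 182 185G/T 195 247 263 315.1 357		L1b1	0
J61	ElJadida	126 187 189 223 264 270 278 293 311 355	73 152 182 185G/T 195 247 263 315.1 357		L1b1	0
J62	ElJadida	17 148 163 187 189 223 278 293 294 311 360	73 89 93 151 182 186C/A 189A/C 247 263 315.1 316		L1c4	0
J63	ElJadida	86 223 278 294 309 390	73 143 146 152 195 198 263 315.1		L2a1	0
J64	ElJadida	167 192 223 278 294 309 390	73 143 146 152 195 263 309.1 315.1		L2a1	0
J65	ElJadida	145 213 223 278 294 390	73 146 152 195 263 315.1		L2a1	0
J66	ElJadida	189 192 223 278 294 309 357 390	73 143 146 152 195 263 315.1		L2a1	0
J67	ElJadida	189 192 223 278 294 309	73 143 146 152 195 263 315.1		L2a1	0
J68	ElJadida	51 172 223 266 278 362	73 263 315.1		L2c1	0
J69	ElJadida	129 183A/C 189 278 300 354 357 390	73 146 150 195 263 309.2 315.1		L2d1	0
J70	ElJadida	209 223	73 152 235 263 309.1 315.1		L3f1a	0
J71	ElJadida	124 223 278 362	73 263 309.1 315.1		L3b1	0
J72	ElJadida	124 223 336	73 152 242 263 315.1		L3d	0
J73	ElJadida	124 223 256	73 152 189 195 263 315.1		L3d1'2'3'	0
J74	ElJadida	124 192 223 256	73 152 189 195 263 309.1 315.1		L3d1'2'3'	0
J75	ElJadida	223 320 399	73 152 195 198 263 315.1		L3e2a	0
J76	ElJadida	223 311 320	73 150 195 198 263 315.1		L3e2a	0
J77	ElJadida	172 183A/C 187 189 223 320	73 150 195 236 263 309.1 315.1 316		L3e2b	0
J78	ElJadida	172 209 223 292 311	73 189 200 263 315.1		L3f1b	0
J79	ElJadida	188 223 292 295 311	73 189 200 263 309.1 315.1		L3f1	0
J80	ElJadida	209 223 292 311 390	73 189 200 263 315.1		L3f1b	0
J81	ElJadida	129 223 256C/A 278 311 362	73 151 152 189A/C 195 263 294 309.1 315.1		L3h1b	0
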