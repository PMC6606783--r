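name	group	M	MNa	M2Na	b_diag	y7	rt	cap	R1	R2	R3	R4	R5	R6	R7	R8	R9	R10	R11	R12	R13	R14	R15	R16	R17	R18	R19	R20	note
Brevicelsin-I	C	1851	1874	948.5	1078	774	28.72	Ac	Aib	Ala	Aib	Ala	Aib	-	Gln	Aib	Lxx	Aib	Gly	Aib	Aib	Pro	Vxx	Aib	Aib	Gln	Gln	Pheol	New: Hypophellin 18, 35, 39: [Lxx]^11^ → [Aib]^11^
Brevicelsin-II	C	1865	1888	955.5	1092	774	29.98	Ac	Aib	Ala	Vxx	Ala	Aib	-	Gln	Aib	Lxx	Aib	Gly	Aib	Aib	Pro	Vxx	Aib	Aib	Gln	Gln	Pheol	New: HPV-9,−12,−20b: [Ala]^3^ → [Vxx]^3^, [Lxx]^11^ → [Aib]^11^
Brevicelsin-III	C	1852	1875	949	1078	775	30.56	Ac	Aib	Ala	Aib	Ala	Aib	-	Gln	Aib	Lxx	Aib	Gly	Aib	Aib	Pro	Vxx	Aib	Aib	Glu	Gln	Pheol	New: Hypophellin 38: [Lxx]^11^ → [Aib]^11^
Brevicelsin-IV	C	1865	1888	955.5	1078	788	31.82	Ac	Aib	Ala	Aib	Ala	Aib	-	Gln	Aib	Lxx	Aib	Gly	Aib	Aib	Pro	Vxx	Aib	Vxx	Gln	Gln	Pheol	New: Hypophellin 20, 40: [Lxx]^11^ → [Aib]^11^
Brevicelsin-V	C	1879	1902	962.5	1092	788	32.82	Ac	Aib	Ala	Aib	Ala	Vxx	-	Gln	Aib	Lxx	Aib	Gly	Aib	Aib	Pro	Vxx	Aib	Vxx	Gln	Gln	Pheol	New: Hypophellin 22, 45: [Lxx]^11^ → [Aib]^11^ (Positional isomer of Brevicelsin VIII)
Brevicelsin-VI	C	1865	1888	955.5	1092	774	33.20	Ac	Aib	Ala	Aib	Ala	Vxx	-	Gln	Aib	Lxx	Aib	Gly	Aib	Aib	Pro	Vxx	Aib	Aib	Gln	Gln	Pheol	New: Hypophellin 4: [Lxx]^11^ → [Aib]^11^
Brevicelsin-VII	C	1866	1889	956	1078	789	33.65	Ac	Aib	Ala	Aib	Ala	Aib	-	Gln	Aib	Lxx	Aib	Gly	Aib	Aib	Pro	Vxx	Aib	Vxx	Glu	Gln	Pheol	New: Hypophellin 21, 43: [Lxx]^11^ → [Aib]^11^
Brevicelsin-VIII	C	1879	1902	962.5	1092	788	36.19	Ac	Aib	Ala	Aib	Ala	Vxx	-	Gln	Aib	Lxx	Aib	Gly	Aib	Aib	Pro	Vxx	Aib	Vxx	Gln	Gln	Pheol	New: (Positional isomer of Brevicelsin V)
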