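coordinate	snp_id	species	effect	dbsnp
15:g.22841716T>G	BCO2.1	B. indicus	Synonymous
15:g.22877552G>A	BCO2.2	B. taurus	Stop	rs109226280
15:g.22878937G>A	BCO2.3	B. taurus	Nonsynonymous	rs445248588
15:g.22886751A>T	BCO2.4	B. taurus	Stop	rs475149853
15:g.22886781G>A	BCO2.5	B. indicus	Nonsynonymous
15:g.22887879G>A	BCO2.6	B. indicus	Nonsynonymous
15:g.22902367G>A	BCO2.7	B. taurus	Synonymous	rs468029187
15:g.22903083C>T	BCO2.8	B. taurus	Nonsynonymous	rs463702615
15:g.22903195A>G	BCO2.9	B. indicus	Synonymous
15:g.22904160C>T	BCO2.10	B. indicus	Nonsynonymous
15:g.22904161A>T	BCO2.11	B. indicus	Nonsynonymous
15:g.22905346T>C	BCO2.12	B. indicus	Nonsynonymous
17:g.53180716C>G	SCARB1.1	B. taurus	Upstream variant	rs211588107
17:g.53180716C>G	SCARB1.2	B. indicus	Upstream variant
17:g.53181068C>G	SCARB1.3	B. indicus	Nonsynonymous
17:g.53229545A>C	SCARB1.4	B. indicus	Nonsynonymous
17:g.53237728A>G	SCARB1.5	B. taurus	Synonymous	rs210238050
17:g.53237728A>G	SCARB1.6	B. indicus	Synonymous
17:g.53237845T>C	SCARB1.7	B. taurus	Synonymous	rs210829935
17:g.53237845T>C	SCARB1.8	B. indicus	Synonymous
17:g.53242822C>A	SCARB1.9	B. taurus	Synonymous	rs377844543
17:g.53242843C>T	SCARB1.10	B. indicus	Synonymous
17:g.53242852C>T	SCARB1.11	B. indicus	Synonymous
17:g.53242906C>T	SCARB1.12	B. taurus	Synonymous	rs478582082
17:g.53245654G>A	SCARB1.13	B. taurus	Synonymous	rs211138720
17:g.53245654G>A	SCARB1.14	B. indicus	Synonymous
17:g.53258090A>G	SCARB1.15	B. indicus	Synonymous
17:g.53263896C>T	SCARB1.16	B. indicus	Synonymous
18:g.7930930C>T	BCMO1.1	B. taurus	Upstream gene variant	rs110137311
18:g.7938090G>A	BCMO1.2	B. taurus	Nonsynonymous/stop	rs210669227
18:g.7938092G>A	BCMO1.3	B. indicus	Synonymous
18:g.7942847T>C	BCMO1.4	B. indicus	Synonymous
18:g.7942924G>C	BCMO1.5	B. indicus	Nonsynonymous
18:g.7944544C>A	BCMO1.6	B. taurus	Synonymous	np
18:g.7944547G>A	BCMO1.7	B. indicus	Synonymous
18:g.7944577C>T	BCMO1.8	B. indicus	Synonymous
18:g.7947135G>C	BCMO1.9	B. indicus	Nonsynonymous
18:g.7947229C>T	BCMO1.10	B. taurus	Synonymous	rs381162140
18:g.7947229C>T	BCMO1.11	B. indicus	Synonymous
18:g.7947242G>A	BCMO1.12	B. taurus	Nonsynonymous	rs209658446
18:g.7949278A>G	BCMO1.13	B. indicus	Synonymous
18:g.7949326T>C	BCMO1.14	B. indicus	Synonymous
18:g.7949381A>G	BCMO1.15	B. taurus	Nonsynonymous	rs444976967
18:g.7962378C>G	BCMO1.16	B. indicus	Nonsynonymous
jcf7180021617284:g.785353G>A	BCO2.13	Bubalus bubalis	Synonymous
jcf7180021617284:g.785395C>T	BCO2.14	B. bubalis	Synonymous
jcf7180021617284:g.787642T>C	BCO2.15	B. bubalis	Nonsynonymous
jcf7180021617284:g.788450C>T	BCO2.16	B. bubalis	Synonymous
jcf7180021617284:g.845577G>A	BCO2.17	B. bubalis	Synonymous
jcf7180021617284:g.847449G>A	BCO2.18	B. bubalis	Nonsynonymous
jcf7180021616390:g.1200693C>T	SCARB1.17	B. bubalis	Synonymous
jcf7180021616390:g.1226834G>T	SCARB1.18	B. bubalis	Nonsynonymous
jcf7180021616390:g.1226890G>C	SCARB1.19	B. bubalis	Synonymous
jcf7180021616390:g.1226924A>G	SCARB1.20	B. bubalis	Nonsynonymous
jcf7180021616390:g.1226944G>A	SCARB1.21	B. bubalis	Synonymous
jcf7180021616390:g.1231985C>T	SCARB1.22	B. bubalis	Nonsynonymous
jcf7180021616390:g.1235067C>T	SCARB1.23	B. bubalis	Synonymous
jcf7180021616390:g.1235151G>A	SCARB1.24	B. bubalis	Synonymous
jcf7180021616390:g.1283516A>C	SCARB1.25	B. bubalis	Synonymous
jcf7180021615735:g.3038221G>T	BCMO1.17	B. bubalis	Missense
jcf7180021615735:g.3038243C>T	BCMO1.18	B. bubalis	Synonymous
jcf7180021615735:g.3040767G>T	BCMO1.19	B. bubalis	Synonymous
jcf7180021615735:g.3051607C>T	BCMO1.20	B. bubalis	Synonymous
jcf7180021615735:g.3062829G>C	BCMO1.21	B. bubalis	Nonsynonymous
jcf7180021615735:g.3062850G>A	BCMO1.22	B. bubalis	Synonymous
jcf7180021615735:g.3062908G>A	BCMO1.23	B. bubalis	Nonsynonymous
jcf7180021615735:g.3068901A>G	BCMO1.24	B. bubalis	Synonymous
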