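sample_id	peptide	abundance_pct	is_novel
H1	KIISSLSKNTIHNNNYKYNYNNNNNYNNNYKKLQYYNINYIEQIP	53.4	FALSE
H1	KIISSLSNKTIHNNNNYKKLYYNINYIEQIP	9.7	FALSE
H1	KIISSLSNNYNYSNYNNYNNNYNNYKKLYYNINYIEQIP	8.9	FALSE
H2	KIISSLSNSCNYSNNYYNKKLYYNIINIEQIP	53.7	FALSE
H2	KIISSLSNNYNYSNYNNYNNNYNNYKKLYYNINYIEQIP	30.2	FALSE
H2	KIISSLSNKTIHNNNNYKPYYNINYIEQIP	7.7	FALSE
H3	KIISSLSNNYKYSNYNNYNNYNNKKLYYNIINIEQIP	40.0	TRUE
H3	KIISSLSNKTIHNNNNYNNYKKLYYNIINIEQIP	12.4	TRUE
H3	KIISSLSNKTIHNNNYKYNYNNNNNYKKLQYYNIINIEQIP	6.3	FALSE
H4	KIISSLSNKTIHNNNNYKPYYNINYIEQIP	83.6	FALSE
H5	KIISSLSSNYNSNNYNNYNNYKQLCYNINYIEQIP	39.6	FALSE
H5	KIISSLSNNYKYSNYNNYNNYNKKLYYKNYIINIEQIP	12.0	FALSE
H5	KIISSLSNNYNYNNKYNYNNNYNKKLYYNIINIEQIP	8.5	FALSE
H6	KIISSLSNKTIHNNNNYKPYYNINYIEQIP	93.1	FALSE
H7	KIISSLSNNYNYNNKYNYNNNYNKKLYYNIINIEQIP	38.2	FALSE
H7	KIISSLSNKTIHNNNKYNYNNNYNNNCKKLYYNINYIEQIP	8.9	TRUE
H8	KIISSLSNKTIHNNNNYKPYYNINYIEQIP	33.3	FALSE
H8	KIISSLSSNYNSNNYNNYNNYKQLCYNINYIEQIP	25.9	FALSE
H8	KITSSLSNNYNSNNYNKYNYNNSKKLYYNINYIEQIP	13.2	FALSE
H8	KIISSLSNKTIHNNNNYKYNYNNNNYKNYNNYKKLYYNINYIEQIP	5.8	FALSE
H9	KIISSLSNKTIHNNNNYKYNYNNNNYKPYYNINYIEQIP	45.0	FALSE
H9	KIISSLSNKTIHNNNNYKYNYNNNYNNNNYSKKLYYNINYIEQIP	10.3	TRUE
H9	KIISSLSNNYISNISNYNNNNNSKKLYYNINYIEQIP	5.2	FALSE
H10	KIISSLSNSCNYSNNYYNKKLYYNIINIEQIP	17.6	FALSE
H11	KIISSLSSNYNSNNYNNYNNYKQLCYNINYIEQIP	43.8	FALSE
H11	KIISSLSNKTIHNNNNYKPYYNINYIEQIP	32.5	FALSE
H11	KIISSLSNNYNYNNKYNYNNNYNKKLYYNIINIEQIP	6.7	FALSE
H12	KITSSLSNNYNSNSYNNYNNNYKKLQYYNIINIEQIP	37.5	FALSE
H12	KIISSLSNNYNYSNYNNYNNYNNNYNNYNNNYNNYKKLYYNINYIEQIP	31.5	FALSE
H12	KIISSLSNKTIHNNNNYKYNYNNNNYNNNNYNNNYNNNCKKLYYNINYIEQIP	5.4	FALSE
H12	KIISSLSNNYKYSNYNNYNNYNNNSKKLYKNYIINIEQIP	5.3	FALSE
H12	KIISSLSNSCNYSNNYYNKKLYYNIINIEQIP	5.1	FALSE
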