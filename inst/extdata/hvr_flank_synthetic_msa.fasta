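>hvr_synthetic_01
KIISSLS--------KNTIHNNNYKYNYNNNNNYNNNYKKLQYYNINYIEQIP
>hvr_synthetic_02
KIISSLS----------------------NKTIHNNNNYKKLYYNINYIEQIP
>hvr_synthetic_03
KIISSLS--------------NNYNYSNYNNYNNNYNNYKKLYYNINYIEQIP
>hvr_synthetic_04
KIISSLS---------------------NSCNYSNNYYNKKLYYNIINIEQIP
>hvr_synthetic_05
KIISSLS-----------------------NKTIHNNNNYKPYYNINYIEQIP
>hvr_synthetic_06
KIISSLS----------------NNYKYSNYNNYNNYNNKKLYYNIINIEQIP
>hvr_synthetic_07
KIISSLS-------------------NKTIHNNNNYNNYKKLYYNIINIEQIP
>hvr_synthetic_08
KIISSLS------------NKTIHNNNYKYNYNNNNNYKKLQYYNIINIEQIP
>hvr_synthetic_09
KIISSLS------------------SNYNSNNYNNYNNYKQLCYNINYIEQIP
>hvr_synthetic_10
KIISSLS---------------NNYKYSNYNNYNNYNKKLYYKNYIINIEQIP
>hvr_synthetic_11
KIISSLS----------------NNYNYNNKYNYNNNYNKKLYYNIINIEQIP
>hvr_synthetic_12
KIISSLS------------NKTIHNNNKYNYNNNYNNNCKKLYYNINYIEQIP
>hvr_synthetic_13
KITSSLS----------------NNYNSNNYNKYNYNNSKKLYYNINYIEQIP
>hvr_synthetic_14
KIISSLS-------NKTIHNNNNYKYNYNNNNYKNYNNYKKLYYNINYIEQIP
>hvr_synthetic_15
KIISSLS--------------NKTIHNNNNYKYNYNNNNYKPYYNINYIEQIP
>hvr_synthetic_16
KIISSLS--------NKTIHNNNNYKYNYNNNYNNNNYSKKLYYNINYIEQIP
>hvr_synthetic_17
KIISSLS----------------NNYISNISNYNNNNNSKKLYYNINYIEQIP
>hvr_synthetic_18
KITSSLS----------------NNYNSNSYNNYNNNYKKLQYYNIINIEQIP
>hvr_synthetic_19
KIISSLS----NNYNYSNYNNYNNYNNNYNNYNNNYNNYKKLYYNINYIEQIP
>hvr_synthetic_20
KIISSLSNKTIHNNNNYKYNYNNNNYNNNNYNNNYNNNCKKLYYNINYIEQIP
>hvr_synthetic_21
KIISSLS-------------NNYKYSNYNNYNNYNNNSKKLYKNYIINIEQIP
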