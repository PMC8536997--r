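>known_01
KIISSLSKNTIHNNNYKYNYNNNNNYNNNYKKLQYYNINYIEQIP
>known_02
KIISSLSNKTIHNNNNYKKLYYNINYIEQIP
>known_03
KIISSLSNNYNYSNYNNYNNNYNNYKKLYYNINYIEQIP
>known_04
KIISSLSNSCNYSNNYYNKKLYYNIINIEQIP
>known_05
KIISSLSNKTIHNNNNYKPYYNINYIEQIP
>known_06
KIISSLSNKTIHNNNYKYNYNNNNNYKKLQYYNIINIEQIP
>known_07
KIISSLSSNYNSNNYNNYNNYKQLCYNINYIEQIP
>known_08
KIISSLSNNYKYSNYNNYNNYNKKLYYKNYIINIEQIP
>known_09
KIISSLSNNYNYNNKYNYNNNYNKKLYYNIINIEQIP
>known_10
KITSSLSNNYNSNNYNKYNYNNSKKLYYNINYIEQIP
>known_11
KIISSLSNKTIHNNNNYKYNYNNNNYKNYNNYKKLYYNINYIEQIP
>known_12
KIISSLSNKTIHNNNNYKYNYNNNNYKPYYNINYIEQIP
>known_13
KIISSLSNNYISNISNYNNNNNSKKLYYNINYIEQIP
>known_14
KITSSLSNNYNSNSYNNYNNNYKKLQYYNIINIEQIP
>known_15
KIISSLSNNYNYSNYNNYNNYNNNYNNYNNNYNNYKKLYYNINYIEQIP
>known_16
KIISSLSNKTIHNNNNYKYNYNNNNYNNNNYNNNYNNNCKKLYYNINYIEQIP
>known_17
KIISSLSNNYKYSNYNNYNNYNNNSKKLYKNYIINIEQIP
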