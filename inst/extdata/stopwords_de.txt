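# custom stopwords: function words + institutional boilerplate
der
die
das
und
im
in
am
an
auf
bei
mit
zur
zum
des
dem
den
ist
sind
sich
bitte
ueber
nach
von
vor
als
bds
zvk
einlage
neuanlage
anlage
zug
kontrolle
lagekontrolle
entfernung
zustand
vena
cava
superior
jugularis
interna
katheterspitze
projektion
herz
mediastinum
regelrecht
lunge
beidseits
ausreichend
beluftet
zwerchfellkuppen
glatt
begrenzt
knoecherner
thorax
intakt
vergleich
voraufnahme
unveraendert
weichteile
unauffaellig
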