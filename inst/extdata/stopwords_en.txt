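# custom stopwords: function words + institutional boilerplate
the
a
an
and
of
with
is
are
at
on
in
over
via
please
after
for
to
central
line
placed
placement
removal
position
check
post
study
internal
jugular
vein
catheter
tip
projects
superior
vena
cava
heart
mediastinum
unremarkable
lungs
well
expanded
bilaterally
diaphragm
smoothly
outlined
bony
intact
unchanged
compared
prior
signs
congestion
soft
tissues
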