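gene	role
METTL3	writer
METTL14	writer
METTL16	writer
RBM15	writer
RBM15B	writer
VIRMA	writer
WTAP	writer
ZC3H13	writer
HNRNPA2B1	reader
HNRNPC	reader
IGF2BP1	reader
IGF2BP2	reader
IGF2BP3	reader
RBMX	reader
YTHDC1	reader
YTHDC2	reader
YTHDF1	reader
YTHDF2	reader
YTHDF3	reader
FTO	eraser
ALKBH5	eraser
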