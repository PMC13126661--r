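parcel	hemisphere	wholebrain_index
11l	left	0
44	left	5
46	left	10
55b	left	15
6a	left	20
6r	left	25
7Am	left	30
7m	left	35
7PL	left	40
7Pm	left	45
8BM	left	50
8C	left	55
9-46d	left	60
a10p	left	65
a9-46v	left	70
AIP	left	75
AVI	left	80
d32	left	85
FEF	left	90
FOP4	left	95
FOP5	left	100
i6-8	left	105
IFJp	left	110
IP1	left	115
IP2	left	120
LIPd	left	125
MIP	left	130
p10p	left	135
p47r	left	140
p9-46v	left	145
PF	left	150
PFm	left	155
PGs	left	160
POS2	left	165
s6-8	left	170
11l	right	180
44	right	185
46	right	190
55b	right	195
6a	right	200
6r	right	205
7Am	right	210
7m	right	215
7PL	right	220
7Pm	right	225
8BM	right	230
8C	right	235
9-46d	right	240
a10p	right	245
a9-46v	right	250
AIP	right	255
AVI	right	260
d32	right	265
FEF	right	270
FOP4	right	275
FOP5	right	280
i6-8	right	285
IFJp	right	290
IP1	right	295
IP2	right	300
LIPd	right	305
MIP	right	310
p10p	right	315
p47r	right	320
p9-46v	right	325
PF	right	330
PFm	right	335
PGs	right	340
POS2	right	345
s6-8	right	350
caudate	left	360
putamen	left	361
thalamus	left	362
caudate	right	370
putamen	right	371
thalamus	right	372
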