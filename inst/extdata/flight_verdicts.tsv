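gene_symbol	gene_group	campaign	cond_a	cond_b	symbol
ABCA5	abc_transporter	PFC	H/W	1g	+
ABCA5	abc_transporter	PFC	1g	1.8g	+
ABCA5	abc_transporter	PFC	1.8g	ug	+
ABCA5	abc_transporter	PFC	1g	ug	+
ABCA5	abc_transporter	TEXUS	H/W	BL	+
ABCA5	abc_transporter	TEXUS	BL	ug	+
ABCA5	abc_transporter	TEXUS	H/W	ug	+
ABCA9	abc_transporter	PFC	H/W	1g	+
ABCA9	abc_transporter	PFC	1g	1.8g	+
ABCA9	abc_transporter	PFC	1.8g	ug	+
ABCA9	abc_transporter	PFC	1g	ug	+
ABCA9	abc_transporter	TEXUS	H/W	BL	+
ABCA9	abc_transporter	TEXUS	BL	ug	+
ABCA9	abc_transporter	TEXUS	H/W	ug	+
ABCC1	abc_transporter	PFC	H/W	1g	+
ABCC1	abc_transporter	PFC	1g	1.8g	+
ABCC1	abc_transporter	PFC	1.8g	ug	+
ABCC1	abc_transporter	PFC	1g	ug	+
ABCC1	abc_transporter	TEXUS	H/W	BL	+
ABCC1	abc_transporter	TEXUS	BL	ug	+
ABCC1	abc_transporter	TEXUS	H/W	ug	+
ABCC12	abc_transporter	PFC	H/W	1g	-
ABCC12	abc_transporter	PFC	1g	1.8g	+
ABCC12	abc_transporter	PFC	1.8g	ug	+
ABCC12	abc_transporter	PFC	1g	ug	+
ABCC12	abc_transporter	TEXUS	H/W	BL	-
ABCC12	abc_transporter	TEXUS	BL	ug	-
ABCC12	abc_transporter	TEXUS	H/W	ug	+
ABCC4	abc_transporter	PFC	H/W	1g	+
ABCC4	abc_transporter	PFC	1g	1.8g	+
ABCC4	abc_transporter	PFC	1.8g	ug	-
ABCC4	abc_transporter	PFC	1g	ug	+
ABCC4	abc_transporter	TEXUS	H/W	BL	+
ABCC4	abc_transporter	TEXUS	BL	ug	-
ABCC4	abc_transporter	TEXUS	H/W	ug	+
ABCD4	abc_transporter	PFC	H/W	1g	-
ABCD4	abc_transporter	PFC	1g	1.8g	-
ABCD4	abc_transporter	PFC	1.8g	ug	+
ABCD4	abc_transporter	PFC	1g	ug	+
ABCD4	abc_transporter	TEXUS	H/W	BL	+
ABCD4	abc_transporter	TEXUS	BL	ug	-
ABCD4	abc_transporter	TEXUS	H/W	ug	+
ABCF2	abc_transporter	PFC	H/W	1g	+
ABCF2	abc_transporter	PFC	1g	1.8g	+
ABCF2	abc_transporter	PFC	1.8g	ug	+
ABCF2	abc_transporter	PFC	1g	ug	+
ABCF2	abc_transporter	TEXUS	H/W	BL	+
ABCF2	abc_transporter	TEXUS	BL	ug	-
ABCF2	abc_transporter	TEXUS	H/W	ug	-
ALB	reference	PFC	H/W	1g	+
ALB	reference	PFC	1g	1.8g	+
ALB	reference	PFC	1.8g	ug	+
ALB	reference	PFC	1g	ug	+
ALB	reference	TEXUS	H/W	BL	+
ALB	reference	TEXUS	BL	ug	+
ALB	reference	TEXUS	H/W	ug	+
B4GALT6	reference	PFC	H/W	1g	+
B4GALT6	reference	PFC	1g	1.8g	+
B4GALT6	reference	PFC	1.8g	ug	+
B4GALT6	reference	PFC	1g	ug	+
B4GALT6	reference	TEXUS	H/W	BL	+
B4GALT6	reference	TEXUS	BL	ug	+
B4GALT6	reference	TEXUS	H/W	ug	+
GAPDH	reference	PFC	H/W	1g	+
GAPDH	reference	PFC	1g	1.8g	+
GAPDH	reference	PFC	1.8g	ug	+
GAPDH	reference	PFC	1g	ug	+
GAPDH	reference	TEXUS	H/W	BL	+
GAPDH	reference	TEXUS	BL	ug	+
GAPDH	reference	TEXUS	H/W	ug	+
HMBS	reference	PFC	H/W	1g	+
HMBS	reference	PFC	1g	1.8g	+
HMBS	reference	PFC	1.8g	ug	+
HMBS	reference	PFC	1g	ug	+
HMBS	reference	TEXUS	H/W	BL	+
HMBS	reference	TEXUS	BL	ug	+
HMBS	reference	TEXUS	H/W	ug	+
RPLP0	reference	PFC	H/W	1g	+
RPLP0	reference	PFC	1g	1.8g	+
RPLP0	reference	PFC	1.8g	ug	+
RPLP0	reference	PFC	1g	ug	-
RPLP0	reference	TEXUS	H/W	BL	+
RPLP0	reference	TEXUS	BL	ug	+
RPLP0	reference	TEXUS	H/W	ug	+
TAP2	abc_transporter	PFC	H/W	1g	-
TAP2	abc_transporter	PFC	1g	1.8g	+
TAP2	abc_transporter	PFC	1.8g	ug	-
TAP2	abc_transporter	PFC	1g	ug	-
TAP2	abc_transporter	TEXUS	H/W	BL	-
TAP2	abc_transporter	TEXUS	BL	ug	-
TAP2	abc_transporter	TEXUS	H/W	ug	-
TBP	reference	PFC	H/W	1g	-
TBP	reference	PFC	1g	1.8g	-
TBP	reference	PFC	1.8g	ug	-
TBP	reference	PFC	1g	ug	-
TBP	reference	TEXUS	H/W	BL	-
TBP	reference	TEXUS	BL	ug	-
TBP	reference	TEXUS	H/W	ug	+
YWHAZ	reference	PFC	H/W	1g	+
YWHAZ	reference	PFC	1g	1.8g	+
YWHAZ	reference	PFC	1.8g	ug	+
YWHAZ	reference	PFC	1g	ug	+
YWHAZ	reference	TEXUS	H/W	BL	+
YWHAZ	reference	TEXUS	BL	ug	+
YWHAZ	reference	TEXUS	H/W	ug	+
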