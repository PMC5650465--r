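animal	sire	dam	gonad_histology	genotype	role
C743	C676	C671	2 ov	G+G+	breeding_stock
C989	C752	C743	2 ov	G+G+	breeding_stock
C3052	C1012	C871	2 ov	G+G+	breeding_stock
C3440	C3428	C3064	2 ov	G+G+	breeding_stock
C3441	C3428	C3064	2 ov	G+G+	breeding_stock
C3567	C3428	C3535	1 ovt, 1 ov	G+G+	xx_dsd
C3542	C3472	C3441	1 ovt, 1 ov	G+G+	xx_dsd
C730	C205	C672	1 ovt, 1 ov	G+G+	xx_dsd
C796	C734	C750	1 ovt, 1 ov	G+/-	xx_dsd
C2021	C734	C871	1 ovt, 1 ov	G+G+	xx_dsd
C2026	C752	C989	1 ovt, 1 ov	G+/-	xx_dsd
C3120	C1012	C3038	1 ovt, 1 ov	G+/-	xx_dsd
C2085	C2005	C871	1 ovt >.5t, 1 ovt <.5t	G+G+	xx_dsd
C726	C676	C333	2 ovt <.5t	G+G+	xx_dsd
C795	C734	C750	2 ovt <.5t	G+G+	xx_dsd
C930	C734	C786	2 ovt <.5t	G+G+	xx_dsd
C964	C752	C854	2 ovt <.5t	G+G+	xx_dsd
C3103	C2005	C3052	2 ovt <.5t	G+G+	xx_dsd
C3104	C2005	C3052	2 ovt <.5t	G+G+	xx_dsd
C3022	C2005	C948	2 ovt <.5t	G+G+	xx_dsd
C3023	C1012	C854	2 ovt <.5t	G+/-	xx_dsd
C3072	C1012	C871	2 ovt <.5t	G+G+	xx_dsd
C3457	C3428	C3052	2 ovt <.5t	G+G+	xx_dsd
C3468	C3428	C3053	2 ovt <.5t	G+G+	xx_dsd
C3497	C3442	C3466	2 ovt <.5t	G+G+	xx_dsd
C3670	C3428	C3596	2 ovt <.5t	G+/-	xx_dsd
C3549	C3472	C3466	2 ovt <.5t	G+G+	xx_dsd
C709	C205	C333	2 ovt >.5t	G+G+	xx_dsd
C798	C734	C750	2 ovt >.5t	G+G+	xx_dsd
C2032	C752	C948	2 ovt >.5t	G+G+	xx_dsd
C3006	C1012	C948	2 ovt >.5t	G+G+	xx_dsd
C783	C734	C743	2 ovt >.5t	G+G+	xx_dsd
C2080	C2005	C854	2 t	G+G+	xx_dsd
C3481	C3428	C3440	2 t	G+G+	xx_dsd
C3582	C3428	C3466	2 t	G+G+	xx_dsd
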