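gene	g	s	strand	stop_completed	n_codons
cox1	0.35	0	+	FALSE	534
cox2	0.35	0	+	TRUE	237
cox3	0.35	0	-	FALSE	492
cob	0.35	0	+	FALSE	475
nad1	0.35	0	-	FALSE	203
nad2	0.35	0	+	FALSE	267
nad3	0.35	0	+	TRUE	377
nad4	0.35	0	-	FALSE	121
nad4l	0.35	0	+	FALSE	162
nad5	0.35	0	+	TRUE	493
nad6	0.35	0	+	FALSE	426
atp6	0.35	0	-	FALSE	473
atp8	0.35	0	+	FALSE	301
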