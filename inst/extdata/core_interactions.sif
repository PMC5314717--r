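NFkB	+	NFkB
NFkB	+	ESE2
NFkB	+	Snai2
NFkB	+	Cyclin
NFkB	-	p53
ESE2	+	ESE2
ESE2	-	Snai2
ESE2	+	Cyclin
ESE2	-	TELase
ESE2	+	NFkB
Snai2	+	Snai2
Snai2	+	TELase
Snai2	-	ESE2
Snai2	-	Cyclin
Snai2	-	E2F
Snai2	-	p16
Snai2	-	p53
Snai2	+	NFkB
p16	+	p16
p16	+	p53
p16	+	Rb
p16	-	Cyclin
p16	+	NFkB
p53	-	E2F
Rb	-	E2F
E2F	+	Cyclin
E2F	-	p16
Cyclin	-	Rb
Cyclin	+	E2F
TELase	-	p16
TELase	-	p53
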