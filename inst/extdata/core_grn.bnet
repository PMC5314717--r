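targets, factors
NFkB, NFkB | ESE2 | Snai2 | p16
ESE2, !Snai2 | (ESE2 & !NFkB)
Snai2, !ESE2 | (Snai2 & NFkB)
p16, !Snai2 & !TELase & (p16 | !E2F)
p53, p16 & !Snai2 & !(NFkB & TELase)
Rb, p16 | !Cyclin
E2F, !Snai2 & ((Cyclin & (!p53 | !Rb)) | (!p53 & !Rb))
Cyclin, E2F | (NFkB & !p16) | (ESE2 & !Snai2 & !p16)
TELase, Snai2 | !ESE2
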