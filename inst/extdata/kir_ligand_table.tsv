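allele	group
A*03:01	A3A11
A*11:01	A3A11
A*23:01	Bw4-80I
A*24:02	Bw4-80I
A*25:01	Bw4-80I
A*32:01	Bw4-80I
B*13:02	Bw4-80T
B*27:05	Bw4-80T
B*37:01	Bw4-80T
B*38:01	Bw4-80I
B*44:02	Bw4-80T
B*44:03	Bw4-80T
B*47:01	Bw4-80I
B*49:01	Bw4-80T
B*51:01	Bw4-80I
B*52:01	Bw4-80I
B*53:01	Bw4-80I
B*57:01	Bw4-80I
B*57:03	Bw4-80I
B*58:01	Bw4-80I
B*59:01	Bw4-80I
C*01:02	C1
C*03:02	C1
C*03:03	C1
C*03:04	C1
C*07:01	C1
C*07:02	C1
C*07:04	C1
C*08:02	C1
C*12:02	C1
C*12:03	C1
C*14:02	C1
C*16:01	C1
C*02:02	C2
C*04:01	C2
C*05:01	C2
C*06:02	C2
C*15:02	C2
C*17:01	C2
C*18:01	C2
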