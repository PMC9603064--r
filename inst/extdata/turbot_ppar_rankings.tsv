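temperature	rank	highExpression	stableExpression	comprehensive
14	1	PPARg	PPARg	PPARg
14	2	PPARa1	PPARa1	PPARa1
14	3	PPARb	PPARa2	PPARa2
14	4	PPARa2	PPARb	PPARb
20	1	PPARb	PPARg	PPARb
20	2	PPARa2	PPARb	PPARa2
20	3	PPARa1	PPARa1	PPARa1
20	4	PPARg	PPARa2	PPARg
23	1	PPARa1	PPARa2	PPARa1
23	2	PPARg	PPARb	PPARg
23	3	PPARa2	PPARa1	PPARa2
23	4	PPARb	PPARg	PPARb
25	1	PPARg	PPARb	PPARg
25	2	PPARa1	PPARa2	PPARa1
25	3	PPARb	PPARg	PPARb
25	4	PPARa2	PPARa1	PPARa2
28	1	PPARa1	PPARb	PPARa1
28	2	PPARg	PPARa2	PPARg
28	3	PPARa2	PPARa1	PPARa2
28	4	PPARb	PPARg	PPARb
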