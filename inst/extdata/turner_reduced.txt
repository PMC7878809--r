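# Reduced nearest-neighbor free-energy parameters (kcal/mol), version 1
# Watson-Crick stacking and loop initiations transcribed from published
# Turner 2004 tables; wobble stacks and terminal mismatches are a smooth
# synthetic completion (this is a reduced table: no dangling ends, no
# coaxial stacking, no special 1x1/2x2 internal loops, no special
# hairpins). Length tables extend beyond 30 by the Jacobson-Stockmayer
# rule dG(n) = dG(30) + extrapolation * ln(n/30).
RT 0.61633
extrapolation 1.0786
terminal_au_gu 0.50
multibranch_offset 3.40
multibranch_branch 0.40
multibranch_unpaired 0.10

[stack]
# outer_pair inner_pair dG; outer = (x_i, x_j), inner = (x_i+1, x_j-1)
AU AU -0.93
AU UA -1.10
AU CG -2.24
AU GC -2.08
AU GU -0.55
AU UG -1.36
UA AU -1.33
UA UA -0.93
UA CG -2.35
UA GC -2.11
UA GU -1.27
UA UG -1.00
CG AU -2.11
CG UA -2.08
CG CG -3.26
CG GC -2.36
CG GU -1.41
CG UG -2.11
GC AU -2.35
GC UA -2.24
GC CG -3.42
GC GC -3.26
GC GU -1.53
GC UG -2.51
GU AU -1.00
GU UA -1.36
GU CG -2.51
GU GC -2.11
GU GU -0.50
GU UG 1.29
UG AU -1.27
UG UA -0.55
UG CG -1.53
UG GC -1.41
UG GU 0.47
UG UG -0.50

[hairpin_init]
3 5.40
4 5.60
5 5.70
6 5.70
7 6.00
8 6.00
9 6.40
10 6.51
11 6.62
12 6.71
13 6.80
14 6.88
15 6.95
16 7.02
17 7.09
18 7.15
19 7.21
20 7.26
21 7.31
22 7.36
23 7.41
24 7.46
25 7.50
26 7.54
27 7.58
28 7.62
29 7.66
30 7.70

[bulge_init]
1 2.80
2 2.80
3 3.20
4 3.60
5 4.00
6 4.40
7 4.57
8 4.71
9 4.84
10 4.95
11 5.05
12 5.15
13 5.23
14 5.31
15 5.39
16 5.46
17 5.52
18 5.58
19 5.64
20 5.70
21 5.75
22 5.80
23 5.85
24 5.90
25 5.94
26 5.98
27 6.02
28 6.06
29 6.10
30 6.14

[internal_init]
2 1.50
3 1.60
4 1.70
5 1.80
6 2.00
7 2.17
8 2.31
9 2.44
10 2.55
11 2.65
12 2.75
13 2.83
14 2.91
15 2.99
16 3.06
17 3.12
18 3.18
19 3.24
20 3.30
21 3.35
22 3.40
23 3.45
24 3.50
25 3.54
26 3.58
27 3.62
28 3.66
29 3.70
30 3.74

[terminal_mismatch]
# closing_pair x_5prime x_3prime dG; mismatch bases adjacent to the
# closing pair read 5'->3' inside the loop
AU A A -0.80
AU A C -0.80
AU A G -1.10
AU A U -0.80
AU C A -0.80
AU C C -0.80
AU C G -0.80
AU C U -0.80
AU G A -1.20
AU G C -0.80
AU G G -1.00
AU G U -0.80
AU U A -0.80
AU U C -0.80
AU U G -0.80
AU U U -1.10
UA A A -0.70
UA A C -0.70
UA A G -1.00
UA A U -0.70
UA C A -0.70
UA C C -0.70
UA C G -0.70
UA C U -0.70
UA G A -1.10
UA G C -0.70
UA G G -0.90
UA G U -0.70
UA U A -0.70
UA U C -0.70
UA U G -0.70
UA U U -1.00
CG A A -1.10
CG A C -1.10
CG A G -1.40
CG A U -1.10
CG C A -1.10
CG C C -1.10
CG C G -1.10
CG C U -1.10
CG G A -1.50
CG G C -1.10
CG G G -1.30
CG G U -1.10
CG U A -1.10
CG U C -1.10
CG U G -1.10
CG U U -1.40
GC A A -1.20
GC A C -1.20
GC A G -1.50
GC A U -1.20
GC C A -1.20
GC C C -1.20
GC C G -1.20
GC C U -1.20
GC G A -1.60
GC G C -1.20
GC G G -1.40
GC G U -1.20
GC U A -1.20
GC U C -1.20
GC U G -1.20
GC U U -1.50
GU A A -0.50
GU A C -0.50
GU A G -0.80
GU A U -0.50
GU C A -0.50
GU C C -0.50
GU C G -0.50
GU C U -0.50
GU G A -0.90
GU G C -0.50
GU G G -0.70
GU G U -0.50
GU U A -0.50
GU U C -0.50
GU U G -0.50
GU U U -0.80
UG A A -0.60
UG A C -0.60
UG A G -0.90
UG A U -0.60
UG C A -0.60
UG C C -0.60
UG C G -0.60
UG C U -0.60
UG G A -1.00
UG G C -0.60
UG G G -0.80
UG G U -0.60
UG U A -0.60
UG U C -0.60
UG U G -0.60
UG U U -0.90
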