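step_score,self_report_pa_score,db_score
25,NA,NA
25,1,26
19,1,20
21,3,24
23,2,25
22,4,26
23,NA,NA
15,5,20
22,5,27
23,5,28
25,NA,NA
12,3,15
19,1,20
20,4,24
9,5,14
24,5,29
24,0,24
22,5,27
24,5,29
21,5,26
21,5,26
25,5,30
23,5,28
22,NA,NA
23,5,28
25,3,28
21,4,25
23,5,28
22,4,26
22,1,23
23,2,25
23,0,23
18,5,23
22,5,27
20,5,25
25,5,30
25,4,29
25,3,28
25,4,29
23,2,25
19,4,23
25,5,30
23,5,28
25,5,30
22,2,24
16,5,21
13,5,18
24,NA,NA
21,5,26
12,5,17
25,1,26
25,5,30
24,3,27
20,1,21
23,0,23
25,5,30
14,3,17
23,2,25
25,5,30
20,1,21
25,2,27
20,0,20
13,5,18
25,NA,NA
21,3,24
22,5,27
5,4,9
21,0,21
25,3,28
18,NA,NA
24,5,29
14,4,18
25,1,26
19,NA,NA
20,0,20
22,5,27
20,0,20
8,2,10
25,0,25
21,NA,NA
25,5,30
25,5,30
19,1,20
21,1,22
14,3,17
25,3,28
25,5,30
25,2,27
16,5,21
25,4,29
21,5,26
20,5,25
21,4,25
25,3,28
25,1,26
25,4,29
25,2,27
23,1,24
25,5,30
25,5,30
24,5,29
22,2,24
23,1,24
25,4,29
23,3,26
13,2,15
11,5,16
25,5,30
NA,3,NA
23,2,25
25,2,27
10,5,15
25,5,30
25,5,30
19,2,21
13,NA,NA
24,5,29
21,1,22
16,5,21
18,5,23
25,NA,NA
25,5,30
24,5,29
20,1,21
19,0,19
22,4,26
11,5,16
23,4,27
14,0,14
15,0,15
17,5,22
24,4,28
24,5,29
14,0,14
23,5,28
25,5,30
21,5,26
20,5,25
22,2,24
13,5,18
18,5,23
25,5,30
20,2,22
18,5,23
19,1,20
12,3,15
14,5,19
25,5,30
23,NA,NA
25,5,30
22,5,27
17,0,17
22,2,24
18,1,19
22,0,22
23,5,28
25,3,28
23,3,26
14,2,16
19,0,19
18,5,23
25,1,26
25,5,30
17,4,21
25,0,25
16,3,19
25,5,30
22,5,27
19,3,22
22,5,27
22,5,27
6,5,11
22,0,22
16,5,21
25,4,29
24,NA,NA
22,5,27
23,5,28
22,4,26
24,5,29
15,3,18
21,4,25
25,3,28
25,0,25
22,2,24
25,1,26
24,5,29
25,3,28
22,0,22
22,5,27
23,1,24
14,5,19
22,5,27
14,5,19
22,5,27
22,0,22
24,2,26
19,3,22
23,0,23
16,1,17
14,0,14
17,1,18
4,5,9
24,5,29
22,5,27
25,2,27
23,5,28
20,3,23
25,4,29
19,2,21
24,5,29
22,5,27
25,5,30
24,5,29
15,2,17
25,5,30
22,5,27
21,1,22
25,0,25
22,1,23
16,5,21
23,4,27
16,1,17
25,5,30
25,3,28
25,4,29
19,3,22
13,5,18
20,0,20
25,5,30
20,2,22
25,5,30
21,0,21
25,NA,NA
25,5,30
22,3,25
21,3,24
18,NA,NA
18,2,20
24,0,24
21,4,25
15,5,20
23,5,28
18,5,23
21,5,26
25,4,29
24,0,24
25,3,28
25,3,28
25,2,27
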