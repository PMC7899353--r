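predilection_score,adequacy_score,intrinsic_motivation_score,pa_competence_score
3.6,2.4,6.0,5.5
4.9,5.5,4.5,5.0
5.5,7.5,5.0,3.0
3.0,4.3,4.5,5.0
NA,5.5,4.0,4.0
3.0,5.5,5.5,2.5
6.2,4.2,6.5,4.5
4.9,4.3,NA,4.5
4.8,3.6,5.5,4.5
4.9,4.3,NA,6.0
3.0,6.2,6.5,4.5
3.0,4.9,5.0,4.0
5.6,4.9,4.0,3.5
4.9,4.2,3.5,4.0
5.5,4.3,NA,4.0
5.5,5.6,6.0,3.5
4.9,4.2,4.5,5.0
4.3,4.8,4.5,3.5
5.6,4.8,5.0,5.0
3.6,6.2,3.0,6.0
4.2,4.3,2.0,5.5
3.6,4.8,2.5,4.0
6.1,4.9,3.5,NA
3.6,3.6,NA,4.5
4.3,6.8,5.0,5.5
4.8,4.3,4.0,NA
5.6,6.2,4.5,5.0
3.0,6.2,7.0,4.0
4.3,4.3,3.5,5.0
4.3,7.5,4.0,5.0
6.1,6.1,NA,4.0
4.9,5.6,6.0,NA
6.2,4.9,5.0,3.0
3.6,6.2,3.5,NA
6.8,6.2,NA,4.5
5.5,2.4,4.5,3.0
5.5,4.2,4.5,6.0
6.2,5.6,NA,NA
3.0,5.6,5.0,1.5
2.4,4.2,5.0,3.5
4.3,5.5,4.0,4.5
3.6,4.9,3.5,6.5
5.5,5.5,6.5,2.5
6.1,4.9,4.0,5.5
NA,4.2,NA,3.5
4.3,6.2,4.5,6.0
2.4,5.6,3.0,4.0
4.9,6.2,NA,6.5
4.9,4.9,5.0,5.5
NA,4.2,5.0,5.0
5.5,3.6,4.0,6.0
4.3,3.7,6.5,NA
4.2,3.6,NA,3.0
4.2,6.8,4.0,5.5
4.9,1.8,5.0,5.0
6.2,3.6,3.5,5.0
4.3,5.6,6.5,5.5
5.5,4.9,2.5,NA
1.8,3.6,6.5,5.0
3.7,3.0,5.0,5.0
4.9,3.6,6.0,5.0
3.7,4.9,5.5,NA
6.8,3.7,4.5,4.5
4.8,4.9,3.5,5.0
6.2,3.6,3.0,4.0
4.2,3.7,2.5,7.0
3.7,4.2,4.5,3.5
1.8,5.6,4.5,5.5
5.5,6.1,4.5,4.5
3.0,4.9,4.5,4.5
5.5,3.6,4.5,NA
4.2,3.0,3.0,2.5
4.8,2.4,4.5,4.0
5.5,4.3,4.5,3.5
4.9,6.1,5.0,4.5
3.6,3.0,5.0,5.0
4.9,3.0,2.5,4.0
3.7,3.7,6.5,4.0
3.6,4.9,5.5,3.5
3.6,4.3,4.5,3.5
4.9,5.4,6.0,2.5
6.2,5.5,2.5,5.0
4.2,3.0,4.0,5.0
3.7,2.4,7.0,3.0
3.7,6.1,4.5,5.0
3.6,5.6,NA,3.0
3.0,5.5,3.5,5.0
2.4,3.7,NA,NA
4.2,4.2,3.5,3.0
4.2,2.4,3.0,3.5
3.0,5.6,4.0,3.5
5.4,4.9,4.0,5.0
5.5,3.0,5.0,5.0
6.2,5.6,5.0,NA
4.3,4.9,2.5,NA
3.6,3.6,NA,5.0
5.6,4.9,3.5,3.5
6.1,6.8,6.0,5.0
4.9,4.9,1.5,5.0
NA,2.4,6.5,4.0
4.2,5.6,5.5,NA
5.5,4.8,5.5,3.5
6.8,4.2,5.5,5.0
4.8,3.0,4.0,4.5
4.9,4.9,4.0,5.5
4.9,3.0,4.0,7.5
4.9,3.0,NA,4.0
2.4,3.7,3.0,5.0
4.8,4.9,NA,NA
3.0,3.7,4.0,4.0
3.6,6.2,5.0,6.0
3.6,4.9,5.5,NA
4.9,5.5,3.5,5.5
3.6,5.6,4.0,6.0
4.3,5.6,3.0,5.5
3.7,4.8,4.0,3.0
2.4,3.7,6.5,4.0
3.0,6.2,3.5,3.5
3.6,3.0,6.0,4.0
4.2,5.4,3.0,6.0
4.3,4.9,4.5,3.5
4.3,3.6,6.0,4.0
6.8,5.4,NA,NA
5.6,3.0,3.0,5.0
4.9,4.8,3.5,6.0
6.2,3.6,NA,7.0
3.0,4.8,5.0,4.0
3.0,4.2,3.0,4.5
5.5,4.2,NA,4.5
3.6,2.4,5.5,2.5
4.2,4.9,5.5,NA
3.7,4.3,6.5,2.5
6.1,6.2,4.0,7.5
3.7,2.4,NA,4.5
3.6,4.9,5.0,4.0
6.2,4.9,5.0,4.0
6.1,4.9,5.0,NA
4.8,4.2,NA,3.0
3.6,4.9,3.0,4.0
4.9,5.5,2.5,5.5
1.8,4.9,NA,NA
5.6,5.5,4.0,4.0
3.0,7.5,6.0,3.5
4.9,5.6,5.0,4.5
4.9,5.5,5.0,3.5
4.8,3.0,3.5,5.0
3.0,4.9,4.5,3.0
4.8,6.1,5.0,NA
4.2,4.9,NA,5.5
4.9,5.5,4.5,4.5
2.4,3.0,2.5,5.5
5.5,5.6,4.0,3.5
3.7,6.2,4.0,6.0
4.3,4.9,5.5,5.0
3.6,4.3,3.0,6.5
3.0,4.9,7.0,6.0
4.8,5.6,5.0,4.0
5.5,4.2,5.0,2.0
7.5,2.4,5.0,4.0
4.9,5.5,NA,NA
4.8,4.9,5.5,2.5
4.2,3.7,7.5,4.5
3.0,4.3,4.0,4.5
2.4,4.3,2.5,5.0
5.5,4.9,3.5,6.0
2.4,4.3,5.5,5.5
5.5,6.1,NA,2.0
6.1,4.8,4.5,7.0
3.6,4.9,6.0,NA
5.5,5.5,5.0,3.5
4.3,6.2,5.0,3.5
4.2,6.1,5.5,NA
4.3,3.6,2.5,5.0
NA,2.4,4.5,NA
6.1,3.6,5.5,5.5
3.6,4.9,2.0,6.0
4.9,6.2,5.0,5.5
5.6,4.3,7.0,5.0
3.7,4.3,NA,4.0
2.4,4.2,6.0,4.0
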