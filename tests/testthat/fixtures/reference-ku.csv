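pa_guideline_score,crf_means_score,ms_means_score,sports_skill_score,fill_in_the_blanks_score,ku_score
0,0,0,0,1,1.000000
1,0,0,1,5,7.000000
0,0,1,1,2,4.000000
0,1,0,0,5,6.000000
0,1,0,0,5,6.000000
0,0,1,0,3,4.000000
1,1,1,0,3,6.000000
0,0,0,0,3,3.000000
0,0,0,1,3,4.000000
0,0,0,0,4,4.000000
0,1,1,1,5,8.000000
0,1,1,0,4,6.000000
0,0,1,0,3,4.000000
0,0,0,0,4,4.000000
0,0,1,1,4,6.000000
0,1,0,0,3,4.000000
0,0,0,0,2,2.000000
0,0,0,1,2,3.000000
0,0,0,1,3,4.000000
0,0,0,0,4,4.000000
0,0,0,0,3,3.000000
0,1,0,0,3,4.000000
0,0,0,0,4,4.000000
0,0,0,0,1,1.000000
0,0,0,0,5,5.000000
1,0,0,0,4,5.000000
1,0,0,0,6,7.000000
0,0,0,1,4,5.000000
0,0,0,1,4,5.000000
0,1,0,0,4,5.000000
0,0,0,0,4,4.000000
0,0,0,1,4,5.000000
0,0,0,0,1,1.000000
1,0,0,0,4,5.000000
1,0,0,1,4,6.000000
0,0,0,0,2,2.000000
0,0,0,0,4,4.000000
0,0,0,0,4,4.000000
0,0,0,0,3,3.000000
1,0,0,0,5,6.000000
0,0,0,0,4,4.000000
0,0,0,0,3,3.000000
0,0,1,0,4,5.000000
1,0,0,0,3,4.000000
0,0,1,0,5,6.000000
1,0,0,1,5,7.000000
0,0,0,0,4,4.000000
0,1,0,1,5,7.000000
1,0,0,0,2,3.000000
0,0,0,0,3,3.000000
0,0,0,0,4,4.000000
0,0,1,0,4,5.000000
0,0,1,0,2,3.000000
0,1,0,0,3,4.000000
0,0,1,0,6,7.000000
0,1,0,0,3,4.000000
0,1,1,1,3,6.000000
0,1,1,0,5,7.000000
1,0,0,0,5,6.000000
1,0,1,0,2,4.000000
0,0,0,0,6,6.000000
0,0,0,0,2,2.000000
0,0,0,0,2,2.000000
0,0,0,0,4,4.000000
0,1,1,0,2,4.000000
0,0,1,0,4,5.000000
0,0,1,1,3,5.000000
1,0,1,1,3,6.000000
0,1,0,1,6,8.000000
0,1,1,0,2,4.000000
0,0,1,0,3,4.000000
0,1,1,0,5,7.000000
1,1,0,0,5,7.000000
0,0,1,0,3,4.000000
1,1,0,1,3,6.000000
0,0,0,0,2,2.000000
0,0,0,0,5,5.000000
0,0,0,1,2,3.000000
1,0,0,0,3,4.000000
1,0,0,1,3,5.000000
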