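pacer_score,plank_score,camsa_score,pc_score,pc_interpretation,pc_status
3,10,5.357143,19.5,achieving,complete
6,10,3.571429,24.0,excelling,complete
10,0,9.285714,15.0,progressing,complete
7,10,5.000000,22.0,excelling,complete
10,10,6.785714,30.0,excelling,complete
2,9,NA,16.5,progressing,missing protocol
5,1,NA,9.0,beginning,missing protocol
10,10,7.857143,30.0,excelling,complete
6,0,4.285714,9.0,beginning,complete
NA,3,8.571429,NA,NA,incomplete
10,10,5.357143,30.0,NA,missing interpretation
10,10,8.571429,30.0,excelling,complete
7,10,8.571429,25.5,NA,missing interpretation
3,10,9.285714,19.5,NA,missing interpretation
NA,10,6.428571,NA,NA,incomplete
10,10,9.285714,30.0,excelling,complete
10,10,NA,30.0,excelling,missing protocol
10,10,6.428571,30.0,excelling,complete
10,0,3.214286,15.0,progressing,complete
10,10,3.571429,30.0,excelling,complete
10,10,6.428571,30.0,excelling,complete
10,5,5.714286,22.5,excelling,complete
10,3,8.928571,19.5,achieving,complete
9,10,7.500000,28.5,NA,missing interpretation
0,9,NA,13.5,NA,missing interpretation
10,10,8.571429,30.0,NA,missing interpretation
10,10,NA,30.0,excelling,missing protocol
10,0,8.214286,15.0,NA,missing interpretation
10,10,10.000000,30.0,excelling,complete
10,5,2.857143,22.5,achieving,complete
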