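subject,session,mean_mm,sd_mm
1,1,33.0,7.9
1,2,27.5,4.1
1,3,19.2,0.6
2,1,22.1,2.7
2,2,19.7,2.0
2,3,16.8,2.9
3,1,25.4,5.5
3,2,29.1,5.0
3,3,26.1,4.8
4,1,44.6,4.8
4,2,48.2,5.8
4,3,38.5,5.1
5,1,49.4,3.4
5,2,45.9,4.1
5,3,55.6,6.5
6,1,46.9,4.9
6,2,44.9,3.6
6,3,37.5,2.1
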