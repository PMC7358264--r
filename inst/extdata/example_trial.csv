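site_id,patient_id,round,outcome
1,1,1,5.2
1,2,1,4.8
2,1,1,5.5
2,2,1,5.2
2,3,1,5
3,1,1,4.7
3,2,1,5.5
3,3,1,5.5
3,4,1,5
3,5,1,5.8
4,1,1,5.1
4,2,1,5
4,3,1,6
4,4,1,4.8
4,5,1,5.6
5,1,1,6.3
5,2,1,5.3
5,3,1,6.5
5,4,1,6.2
1,3,2,5.1
1,4,2,5
1,5,2,5.3
1,6,2,5.3
1,7,2,5.1
1,8,2,4.6
2,4,2,5.4
2,5,2,5.4
2,6,2,4.9
2,7,2,5.5
3,6,2,5.4
3,7,2,5.3
3,8,2,5.5
4,6,2,6
4,7,2,5.8
5,5,2,5.3
5,6,2,5.4
5,7,2,5.5
5,8,2,5.6
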