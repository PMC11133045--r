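Phase,Session,Scores,Criterion
A,1,7.12,
A,2,9.35,
A,3,8.99,
A,4,12.41,
A,5,9,
A,6,10.78,
B1,7,16.47,15
B1,8,16.11,15
B1,9,15.18,15
B2,10,19.67,20
B2,11,22.11,20
B2,12,23.1,20
B3,13,27.44,25
B3,14,25.43,25
B3,15,22.21,25
B4,16,25.79,30
B4,17,23.95,30
B4,18,29.53,30
B5,19,37.61,35
B5,20,36.76,35
B5,21,24.6,35
B6,22,35.87,40
B6,23,35.21,40
B6,24,40.3,40
B7,25,38.21,45
B7,26,34.33,45
B7,27,46.69,45
B8,28,52.07,50
B8,29,55.59,50
B8,30,50.66,50
B9,31,57.3,55
B9,32,47.59,55
B9,33,52.16,55
B10,34,62.99,60
B10,35,49.13,60
B10,36,56.11,60
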