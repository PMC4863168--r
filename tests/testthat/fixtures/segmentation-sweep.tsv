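# frame-level agreement of segment_tracks() with simulation ground truth
# stop-and-go tracks: 60 brownian / 60 flow / 60 brownian frames,
# D = 3.7e-4 um^2/s, noise_sd = 0.02 um, 20 tracks per run, defaults otherwise
v_um_min	seed	agreement
0.45	1	0.6766666666666666
1	1	0.7475
2	1	0.8683333333333333
4	1	0.9183333333333333
8	1	0.9666666666666667
0.45	2	0.685
1	2	0.7466666666666667
2	2	0.865
4	2	0.9225
8	2	0.9691666666666666
0.45	3	0.6783333333333333
1	3	0.7416666666666667
2	3	0.8675
4	3	0.93
8	3	0.9691666666666666
0.45	4	0.6783333333333333
1	4	0.7416666666666667
2	4	0.8666666666666667
4	4	0.9325
8	4	0.9716666666666667
0.45	5	0.6783333333333333
1	5	0.7441666666666666
2	5	0.8608333333333333
4	5	0.9358333333333333
8	5	0.9683333333333334
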