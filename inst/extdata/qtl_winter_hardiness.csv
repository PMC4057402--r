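chrom,pos,si_lo,si_hi,pg,pg_DH06,pg_DH07,pg_EAW74,pg_EAW78
2A,62.1,58.0,63.8,2.2,0.6,3.6,0.3,0.2
5A,52.7,51.6,52.9,14.1,1.2,0.2,40.2,0.0
7A,63.6,63.5,63.7,2.3,0.0,0.5,3.1,3.3
1B,54.1,53.2,54.3,12.5,14.4,17.4,7.6,18.8
2B,107.4,107.0,108.1,2.9,4.5,3.4,3.1,4.1
5B,39.9,39.3,40.7,2.8,2.1,2.2,5.3,1.3
6B,56.8,55.3,58.7,2.0,1.5,6.8,0.7,0.2
4R,35.7,35.3,36.1,2.6,0.0,0.2,4.8,2.3
5R,58.9,58.6,58.9,24.1,44.8,20.4,3.4,29.8
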