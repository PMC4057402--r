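chrom,pos,si_lo,si_hi,pg,pg_DH06,pg_DH07,pg_EAW74,pg_EAW78
1A,80.1,80.0,80.4,2.6,0.0,8.3,1.4,1.5
5A,52.5,51.6,52.9,12.4,2.1,0.5,40.2,0.3
6A,14.5,14.0,14.6,2.2,0.0,13.1,0.0,0.2
7A,71.6,66.8,79.3,3.4,0.4,4.1,3.8,1.9
1B,54.1,53.2,54.3,16.3,19.0,15.4,5.1,25.3
2B,79.3,78.5,79.3,2.9,5.6,3.4,4.3,4.1
6B,57.8,55.3,58.7,1.9,1.6,2.5,3.1,0.6
4R,25.3,25.1,25.3,3.0,0.8,4.5,6.9,0.0
5R,55.6,55.4,56.2,14.7,31.7,9.0,1.5,18.2
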