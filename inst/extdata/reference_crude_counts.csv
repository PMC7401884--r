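lbtd_bin,stratum,n,deaths
<10.1,unknown,1067,69
<10.1,D3,144,0
<10.1,M3,41,11
<10.1,le80,673,46
<10.1,gt80,579,141
10.1-12.0,unknown,721,96
10.1-12.0,D3,128,4
10.1-12.0,M3,52,11
10.1-12.0,le80,433,28
10.1-12.0,gt80,468,111
12.1-14.0,unknown,591,160
12.1-14.0,D3,98,3
12.1-14.0,M3,80,21
12.1-14.0,le80,410,37
12.1-14.0,gt80,359,75
14.1-16.0,unknown,405,173
14.1-16.0,D3,71,4
14.1-16.0,M3,94,36
14.1-16.0,le80,264,14
14.1-16.0,gt80,306,69
16.1-18.0,unknown,227,121
16.1-18.0,D3,48,7
16.1-18.0,M3,85,49
16.1-18.0,le80,147,7
16.1-18.0,gt80,213,39
18.1-28.0,unknown,219,136
18.1-28.0,D3,22,3
18.1-28.0,M3,81,52
18.1-28.0,le80,122,3
18.1-28.0,gt80,200,27
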