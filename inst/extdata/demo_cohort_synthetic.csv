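"id","ghq1","ghq2","ghq3","ghq4","ghq5","ghq6","ghq7","ghq8","ghq9","ghq10","ghq11","ghq12","soc1","soc2","soc3","soc4","soc5","soc6","soc7","soc8","soc9","soc10","soc11","soc12","soc13","bdi1","bdi2","bdi3","bdi4","bdi5","bdi6","bdi7","bdi8","bdi9","health","sex","age"
1,0,2,0,1,0,0,0,0,1,1,0,0,1,1,1,5,5,5,4,7,6,5,6,6,3,0,0,0,0,0,0,0,0,0,"very good","female",19
2,0,3,0,0,2,0,2,1,,2,3,1,4,4,6,4,4,2,5,1,3,3,4,3,5,0,1,2,2,0,1,2,0,0,"bad","female",21
3,0,2,1,1,0,2,0,1,1,3,1,1,2,3,5,3,4,2,5,3,,4,5,2,5,1,1,1,1,1,2,0,0,1,"fair","female",25
4,2,1,1,2,1,1,3,0,1,2,3,1,4,3,4,4,5,2,5,4,4,4,3,4,4,2,0,2,1,,0,1,1,,"bad","female",22
5,3,2,0,0,1,1,1,1,0,,0,1,6,6,3,4,4,2,7,4,4,4,4,4,4,1,0,0,,2,2,0,1,2,"good","female",19
6,0,1,1,3,0,1,3,3,3,2,1,0,5,5,5,6,5,3,4,4,4,3,5,2,4,0,1,0,2,1,1,1,2,1,"bad","female",21
7,1,2,0,1,2,2,0,1,1,0,0,2,4,5,4,5,5,4,2,4,3,3,,4,4,0,0,0,0,0,1,0,0,0,"good","female",20
8,1,1,2,0,1,0,1,1,1,0,1,,3,3,6,,5,7,5,2,6,4,5,5,5,0,0,0,0,1,0,1,2,1,"good","female",22
9,2,0,3,0,0,1,0,0,1,1,1,0,3,4,4,2,6,5,3,4,3,6,2,,5,0,1,0,0,2,0,0,2,0,"good","female",23
10,,0,1,0,1,0,1,0,0,0,0,1,2,3,3,6,6,5,2,3,7,1,4,5,5,0,0,0,0,0,1,0,0,0,"good","female",25
11,1,0,1,0,1,1,0,3,1,1,0,2,2,4,2,4,5,4,3,5,5,5,4,5,5,2,0,1,0,0,0,0,1,0,"good","female",19
12,0,1,0,1,0,0,0,1,2,0,0,1,4,3,2,4,4,5,3,7,6,1,6,5,6,,0,0,0,0,0,0,0,0,"very good","male",18
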