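Time,BGL
11/2/2020 20:23,8.9
11/3/2020 19:53,6.5
11/3/2020 20:08,7.4
11/3/2020 20:23,7.8
11/3/2020 20:39,8.2
11/3/2020 20:54,8.7
11/3/2020 21:08,9.4
11/3/2020 21:23,8.3
11/3/2020 21:38,7.4
11/3/2020 21:55,7.1
11/3/2020 22:10,8.3
11/3/2020 22:25,9.5
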