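year,value
2013,89.5
2014,85.9
2015,80.6
2016,73.0
2017,58.0
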