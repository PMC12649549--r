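peptide,hc10,censored
"W5K/A9W",30.0,FALSE
"W5K01",70.9,FALSE
"W5K02",16.7,FALSE
"W5K03",108.7,TRUE
"W5K04",108.7,TRUE
"W5K05",108.7,TRUE
"W5K06",108.7,TRUE
"W5K07",108.7,TRUE
"W5K08",108.7,TRUE
"W5K09",108.7,TRUE
"W5K10",108.7,TRUE
"W5K11",71.0,FALSE
"W5K12",41.7,FALSE
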