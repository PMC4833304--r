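# synthetic co-expressed pair list matching synthetic_expression.tsv
G00001	G00002
G00003	G00004
G00005	G00006
G00007	G00008
G00009	G00010
G00011	G00012
G00013	G00014
G00015	G00016
G00017	G00018
G00019	G00020
G00021	G00022
G00023	G00024
G00025	G00026
G00027	G00028
G00029	G00030
G00031	G00032
G00033	G00034
G00035	G00036
G00037	G00038
G00039	G00040
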