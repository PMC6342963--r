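# Default avian cone template parameters (editable configuration).
# lambda_max: opsin peak (nm); lambda_mid: oil-droplet 50% point (nm),
# NA = transparent droplet; media: ocular-media curve (U, V or mean).
cone_class	lambda_max	lambda_mid	media
U	371	NA	U
V	405	NA	V
S(U)	445	415	U
S(V)	470	435	V
M	505	515	mean
L	565	570	mean
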