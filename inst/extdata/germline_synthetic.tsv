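gene_id	locus	segment	functional	paralog_canonical
IGKV1-33	IGK	V	TRUE	IGKV1-33
IGKV1D-33	IGK	V	TRUE	IGKV1-33
IGKV1-39	IGK	V	TRUE	IGKV1-39
IGKV1D-39	IGK	V	TRUE	IGKV1-39
IGKV3-11	IGK	V	TRUE	IGKV3-11
IGKV3-20	IGK	V	TRUE	IGKV3-20
IGKV4-1	IGK	V	TRUE	IGKV4-1
IGLV1-36	IGL	V	TRUE	IGLV1-36
IGLV1-44	IGL	V	TRUE	IGLV1-44
IGLV2-14	IGL	V	TRUE	IGLV2-14
IGLV3-1	IGL	V	TRUE	IGLV3-1
IGLV6-57	IGL	V	TRUE	IGLV6-57
IGKJ1	IGK	J	TRUE	IGKJ1
IGKJ2	IGK	J	TRUE	IGKJ2
IGLJ2	IGL	J	TRUE	IGLJ2
IGLJ3	IGL	J	TRUE	IGLJ3
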