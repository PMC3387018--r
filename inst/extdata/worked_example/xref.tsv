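key_type	key_value	field	value
native_id	METLIN:62727	inchi_key	ABCDEFGHIJKLMN-BBBBBBBBSA-N
hmdb_id	HMDB02579	pubchem_cid	44263370
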