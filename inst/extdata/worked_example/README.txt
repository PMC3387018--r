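Worked-example fixture: one bile-acid glucuronide metabolite as exposed by
four record sources with their typical identifier gaps (the Metlin-style
source lacks InChI data; only the LIPID MAPS-style source carries the
PubChem SID; only the HMDB-style source carries the KEGG id). The InChIKeys
are SYNTHETIC placeholders sharing one 14-character skeleton with two
stereo suffixes; all other identifiers are real published ids for this
compound. Query: m/z 624.3401, negative mode ([M-H]-), 10 ppm.
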