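# Synthetic template for curated reference gene lists (TSV: name, member_id).
# The STOP1_regulon and core_PSR entries below are placeholders marking the
# expected format; replace member_id values with curated A. thaliana gene
# identifiers from the literature before running a real screen.
name	member_id
STOP1_regulon	AT0G000010
STOP1_regulon	AT0G000020
STOP1_regulon	AT0G000030
core_PSR	AT0G000110
core_PSR	AT0G000120
core_PSR	AT0G000130
core_PSR	AT0G000140
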