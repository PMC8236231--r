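motif	width	consensus
motif_12	9	DDDMSLWSY
motif_15	50	NNYJPYGFYPAVQYAEDISQNPQHSIQKQTFDDNYGFLDGETTKASGMIW
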