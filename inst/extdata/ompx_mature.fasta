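>OmpX_mature E. coli OmpX, mature chain (UniProt P0A917, residues 24-171)
ATSTVTGGYAQSDAQGQMNKMGGFNLKYRYEEDNSPLGVIGSFTYTEKSRTASSGDYNKN
QYYGITAGPAYRINDWASIYGVVGVGYGKFQTTEYPTYKHDTSDYGFSYGAGLQFNPMEN
VALDFSYEQSRIRSVDVGTWIAGVGYRF
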