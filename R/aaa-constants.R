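# Shared alphabets and scales.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# X in motif patterns is a bounded wildcard over the 20 standard residues
# only: ambiguous residues (X) and stops never satisfy a pattern position.
AA20_CLASS <- paste0("[", paste(AA_STANDARD, collapse = ""), "]")
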