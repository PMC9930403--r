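# Case-insensitive substrings marking repeat-associated annotation hits.
# One keyword per line; lines starting with '#' are ignored.
transposon
retrotransposon
transposase
gag
pol
polyprotein
reverse transcriptase
integrase
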