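protein
factor
family
binding
gene
receptor
domain
subunit
member
type
like
associated
containing
candidate
putative
predicted
expressed
sequence
homolog
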