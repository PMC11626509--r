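# sidecar annotation for synthetic_toy.fasta
accession	SYN_TOY.1
gene	TOY
cds_start	10
cds_end	309
domain	DOM	40	60	synthetic
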