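gene	tissue
NRXN2	brain
NRXN2	substantia nigra
RFT1	brain
CFAP65	testis
TEP1	ubiquitous
CCNF	ubiquitous
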