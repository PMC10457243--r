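plasmid	unit_group_bp	consensus
pA3H1	22	CATAAAGCTACGTTTAGCGACC
pA3H2	22	CATACCCTTACGTTTAGCGACC
pA3H4	22	CATACCACTACGTCTATCGACC
pA3H8	22	CATATGACGACAAATTCCTACC
pA3H9	22	CT(A/T)(T/G)ATGACTACAAATCCTTAC
pA3H10	22	(G/C)ATA(A/G)(A/G)(C/T)ATACGTTTATACACC
pA3H5	21	(A/T)(A/T)(A/G)AAGCTAC(A/G)(A/T)(C/T)(A/T)ATCATA(A/G)
pA3H11	20	AGAAAAAACAGTAAATGAGC
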