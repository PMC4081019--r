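# External data

This directory intentionally ships no experimental structures.

To run the full acceptance checks against the real ubiquitin fold, place the
crystal structure of the ubiquitin monomer (PDB entry 1UBQ, downloadable from
https://files.rcsb.org/download/1UBQ.pdb) here as `1ubq.pdb` **before
installing the package**.  The test suite and `scripts/acceptance.R` pick it
up automatically; without it they fall back to the synthetic
ubiquitin-sequence surrogate generated by `make_ub_monomer()`, whose compact
fold is idealized and does not reproduce fold-specific quantities (the M1-K63
backbone distance, the native contact map, linkage-site geometry).
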