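# extdata

No data files are bundled: every fixture in the test suite is generated in
code by the package's own simulator.

To run the optional real-data check of the published MC#1 AT percentage,
place the deposited MC#1 minicircle sequence (GenBank accession JX082260)
here as `JX082260_MC1.fasta` and re-run the test suite.
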