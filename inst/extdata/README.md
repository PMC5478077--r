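Plain-text data fetched at setup time lives here.

`accessions/` (created by scripts/fetch_accessions.R) holds the 11 GenBank
mitogenome FASTA files and simplified feature tables used by the
panel-dependent acceptance checks; it is intentionally absent from the
repository because the records are not redistributed.
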