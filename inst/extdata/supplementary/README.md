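# Supplementary study matrices (not distributed)

The original study's two character matrices are not redistributed with this
package. To enable the corresponding codability checks, place them here as:

- `supp1.nex` — the broad-sampling matrix (fossil codable for 134 characters)
- `supp2.nex` — the denser coccinelloid matrix (fossil codable for 44 characters)

with the fossil taxon labelled `Yassibum`. The files may be in any dialect
accepted by `parse_matrix()` (NEXUS characters block, interleaved or not, or
a bare whitespace-delimited table).
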