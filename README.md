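# snpground

Grounding SNP mentions in biomedical text to variant-database records.

A single nucleotide polymorphism appears in the literature under many
guises: as a protein-level substitution (`E298D`, `Glu(298)→Asp`), as a
nucleotide-level substitution in one of four historical numbering
conventions (`894G>T`, `252+2T>C`, `IVS2+2T>C`, `c.26+2T>C`), or as a
database identifier (`rs1799983`). `snpground` recognizes all of these in
plain text, converts positions among the conventions over explicit gene
models, and grounds each mention to a dbSNP-style record. It is written
for text-mining and curation work where variant mentions must be linked
to stable identifiers, and for anyone who needs the old numbering
conventions made executable.

## The conventions and the matching algorithm

Over a gene model (exons, strand, start-codon and stop-codon positions,
cap site) the package computes, for any reference position *g*:

* **cap-site transcript numbering (1993):** cap = +1, upstream −1, −2, …
  (no 0), exonic bases counted consecutively, intronic bases written
  `anchor±d` relative to the nearer exon edge;
* **genomic numbering:** the absolute 1-based reference position;
* **IVS convention:** exonic numbering from the A of the start codon,
  intronic positions `IVSn±d` by intron ordinal;
* **HGVS-style coding numbering:** `c.1…n` over the CDS, negative 5'UTR,
  `*k` in the 3'UTR, `anchor±d` intronic.

A mention is grounded by validating it against every record linked to the
document's genes: the position must resolve (under any convention
compatible with the mention's surface, on any transcript) to the record's
position, and the mention's allele set must be contained in the record's
— after Watson–Crick complementation when the record stores its alleles
on the strand opposite to the gene. Wild-type/mutated order is ignored.
Protein-level positions may be corrected by documented maturation
offsets: +1 for a cleaved initiator methionine, or the length of an
N-terminal Signal/Transit/Peptide/Propeptide feature. Co-located
duplicate records are reported together; rs citations that contradict
their co-mentioned description are flagged with suggested corrections.

## Worked example

```r
library(snpground)

fx <- nos3Fixture()   # an eNOS-like gene and records, one true, three decoys
normalizeDocument(
  "The Glu(298)– –>Asp (E298D; 894G– –>T) polymorphism of eNOS
   has been related with cardiovascular disease.",
  gene_ids = fx$gene_id, store = fx$store)
```

```
  doc_id start end         surface status  rs_ids explanation
1   doc1     4  19 Glu(298)– –>Asp UNIQUE 1799983
2   doc1    21  26           E298D UNIQUE 1799983
3   doc1    28  37       894G– –>T UNIQUE 1799983  scheme=IVS
```

All three co-referent mentions — two protein-level, one
nucleotide-level, written with different arrow dialects — ground to the
same identifier. The `explanation` column records how a match succeeded
(the convention used, any maturation offset, a strand or direction flip).

Coordinate conversion on the worked MECP2-like gene model:

```r
fx <- mecp2Fixture()
sapply(enumerateRepresentations(fx$model, 10490), formatPosition)
#> [1] "252+2"   "g.10490" "IVS2+2"  "c.26+2"
resolvePosition(fx$model, "IVS2+2", "IVS")
#> [1] 10490
```

A command-line wrapper ships in `inst/cli/snpground.R` with subcommands
`tag`, `convert`, `normalize`, `evaluate` and `simulate`.

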