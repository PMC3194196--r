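---
title: "Grounding SNP mentions: models, conventions and design choices"
author: "snpground"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grounding SNP mentions: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpground)
```

# The problem

A single nucleotide polymorphism can be described in text at the protein
level (`E298D`, `Glu(298)→Asp`), at the nucleotide level (`894G>T`,
`IVS2+2T→C`, `c.-225C>A`) or by a database identifier (`rs1799983`).
Normalization means associating each such mention with its unique
variant-database record. The difficulty is that the human mutation
nomenclature changed several times, that databases store alleles on
arbitrary strands, and that authors count residues on mature proteins,
swap wild-type and mutated alleles, and occasionally permute the digits of
an rs number. `snpground` implements the full chain — recognition,
coordinate conversion, record matching with systematic-error recovery, and
evaluation — over explicit gene models and a dbSNP-style record store.
Gene name recognition is deliberately an *input*: callers supply the gene
identifiers mentioned in a document, emulating a perfect upstream gene
tagger, so that the normalizer itself can be assessed in isolation.

# The four position-numbering conventions

All conversions run over a `GeneModel`: exons as 1-based closed reference
intervals, strand, the reference position of the A of the start codon, the
last base of the stop codon, and the transcription start (cap site).
Internally every computation uses a signed "walk" coordinate in which the
gene strand always runs upward, so minus-strand genes are handled by the
same arithmetic; only the final complementation of alleles is
strand-specific.

* **Cap-site transcript numbering (1993).** The 5' cap is +1, upstream
  bases are −1, −2, ... (there is no 0), only exonic bases are counted,
  and intronic positions are written as the transcript coordinate of the
  nearer exon edge plus a signed distance (`252+2`).
* **Genomic numbering.** The absolute 1-based position on the stated
  reference sequence (`4943`); no origin shifting is applied.
* **IVS convention.** Exonic numbering restarts at the A of the start
  codon (+1, upstream negative, no 0); intronic positions are written
  `IVSn±d` with the intron ordinal and the distance to the nearer exon
  boundary (`IVS2+2`).
* **HGVS-style coding numbering.** Coding positions are `c.1..n`, the
  5'UTR is negative, the 3'UTR carries asterisk numbers counted from the
  first base after the stop codon, and intronic positions anchor at the
  nearest exonic coding/UTR coordinate (`c.26+2`, `c.*12-5`).

Three numerical choices the conventions leave open are fixed as follows
and asserted by tests:

* **No position zero.** Upstream numbering jumps from +1 to −1. Whether
  the 1993 convention admitted a zero is unstated in its descriptions; we
  forbid it, matching the "−1, −2, −3" wording of the convention.
* **Equidistant intronic tie-break.** A base exactly mid-intron anchors to
  the 5' exon with a `+` offset. This matches common HGVS practice; the
  historical texts are silent.
* **Upstream continuation.** Positions upstream of the cap still receive
  (negative) transcript-based coordinates by continuing the numbering,
  because published promoter-region mentions (`-3608T>C`, `c.-9610G>A`)
  use exactly that continuation.

`renderPosition()` maps a reference position into a convention,
`resolvePosition()` inverts it, and `enumerateRepresentations()` takes the
union over all conventions and all transcripts of a gene. Rendering is
checked against an independent base-by-base enumeration oracle in the test
suite, and a round-trip identity over more than 10^4 random
(model, position, convention) triples runs as part of acceptance testing.
Resolution accepts intronic descriptions anchored at either flanking exon
(the historical conventions allowed both readings) and fails loudly — an
anchor off the transcript or an intron ordinal that does not exist is an
error, not a silent zero.

# Recognition

Published text mixes arrow dialects (`→`, `-->`, `– –>`, `=>`) and dash
characters (en/em dash, minus sign). `canonicalizeText()` collapses them
to `>` and `-` while keeping a character-level offset map, so all match
spans are reported on the original text. The transformation is idempotent.

Three finder families run on the canonical text:

* **Protein mentions** in one-letter, three-letter, bracketed/arrowed and
  `p.`-prefixed forms. The amino-acid alphabet includes the ambiguous
  `Xle` (mapped to `J`) and the termination spellings `Ter`, `X`, `*`,
  `term`, `amber`, `opal`, `ochre` (mapped to a `*` stop sentinel). A
  configurable stoplist suppresses surfaces that denote other concepts
  (`T47D`, `E2F`, `P4501A`, ...); it ships as an editable text file
  because no complete published list exists.
* **Nucleotide mentions** via a small family of regular expressions
  covering legacy (`894G>T`, `-225C>A`, `252+2T>C`), IVS (`IVS2+2T>C`),
  prefixed (`c.26+2T>C`, `g.-420C>G`, `NM_005957.3:c.123G>T`) and
  multi-allele (`82C>T/G`) forms. The original systems' exact expressions
  were never published; ours are written to cover every documented surface
  form, and the synthetic generator round-trips each of them. Position
  expressions are preserved verbatim; a `c.`/`g.`/`r.` prefix is kept as a
  scheme hint.
* **rs identifiers** with the pattern `[rR][sS][ ]*[1-9][0-9]*`.
  Capitalized matches (`RS6000`) are accepted only when a trigger keyword
  ("mutation", "SNP", "polymorphism", ...) occurs in the document and no
  exclusion word ("strain") does; a blacklist rejects known false
  positives. All three lists are editable config files seeded with the
  documented examples.

Overlapping candidates are resolved longest-match-first with ties broken
by leftmost start, which makes extraction deterministic and prefers
`NM_005957.3:c.123G>T` over its unprefixed suffix.

A one-letter mention whose both residues are nucleotide symbols (`A123T`)
is genuinely ambiguous between the protein and nucleotide levels.
`classifyLevel()` resolves what it can: three-letter or `p.` surfaces are
protein-level; prefixes, IVS forms and signed or two-number positions are
nucleotide-level; for the rest a position heuristic applies — nearly all
annotated protein variants sit below residue 4000, so ambiguous mentions
at or above 4000 are classified nucleotide-level, and the remainder are
pursued along **both** validation paths.

For taggers that emit alleles and locations as separate fragments,
`associateSubentities()` builds (wild, location, mutated) triples. Two
allele fragments joined only by arrow characters (`C>G`) form one intact
substitution unit and attach to their nearest location even across a
listing comma, as in `(-19, C>G)`; an isolated allele, by contrast, never
pairs with a location across a comma, period, semicolon, bracket or
sentence boundary — that veto is exactly what prevents the spurious triple
in `...C>G, 261...`. This split rule is our design: a soft "punishment" of
punctuation was described for the original system without an exact
algorithm, and the unit/veto combination reproduces both documented
outcomes. The sentence splitter is a deliberate `". "`-plus-newline
heuristic; it is only used as a veto here, not for any linguistic
analysis.

# The matching algorithm

For each mention the normalizer pools candidate records linked to *any*
gene supplied for the document and validates the mention against each
candidate:

* **Protein path.** The mention's residue position must equal the
  record's precursor position either directly or after a documented
  maturation offset: +1 when the initiator methionine is cleaved, or the
  length of an N-terminal `Signal`/`Transit`/`Peptide`/`Propeptide`
  feature that starts at residue 1. Candidates are tried weakest first
  (no offset, then initiator Met, then features), so the reported
  explanation is the minimal sufficient one. `Var_seq` features are
  isoform markers and generate no offset: the one documented whole-chain
  `Var_seq` usage cannot be given a defensible arithmetic, so such rows
  permit only the zero offset and are flagged in the fixture notes.
  Unexplained constant offsets (a documented +52 case) remain unmatched —
  there is no fuzzy position tolerance. Records without residue
  information never match protein mentions.
* **Nucleotide path.** The mention's position expression is interpreted
  under every convention compatible with its surface: explicit prefixes
  pin the convention, IVS forms pin IVS, unprefixed signed/two-number
  forms may be any transcript-based convention, and bare integers may
  additionally be genomic. This compatibility matrix is our choice (the
  original is undescribed); it prevents a bare `123A>C` from matching
  IVS-only coordinates while keeping every documented pairing. The
  position validates when any reading resolves to the record's reference
  position on any transcript of the record's genes; the alleles validate
  when the mention's allele set is a **subset** of the record's (handling
  tri- and tetra-allelic records), after complementing the record's
  stored alleles if its orientation is opposite to the gene.
* **Direction agnosticism.** Wild-type/mutated order is ignored on both
  paths, because authors assign wild type by population frequency while
  databases follow the reference sequence.

Distinct matching identifiers determine the outcome status: `UNIQUE`,
`AMBIGUOUS_DUPLICATE` (several ids at the identical reference position —
unmerged duplicate records, reported together), `MULTIPLE_GENES`
(matches on different genes, all reported; also used for the residual
corner of several non-co-located matches on one gene, which the status
vocabulary does not otherwise cover), `NO_MATCH`, and `RS_DIRECT` for
cited identifiers present in the store.

An rs citation co-mentioned with a variant description is additionally
checked for consistency: if the description validates against some other
candidate record but not against the cited one, the citation is flagged
`RS_INCONSISTENT` and the validating ids are suggested. When no record
validates the description at all, we report `unsupported` rather than
inconsistent — absence of evidence is kept distinct from contradiction.

# Evaluation

`evaluateNormalization()` scores predicted (mention, identifier) pairs
against a gold standard keyed by document and surface (or span). Reported
percentages round half away from zero to one decimal. Note that half-up
rounding reproduces reference figures such as 98.1 % (356/363) and 94.7 %
(268/283) exactly, while a ratio like 356/527 = 67.55 % prints as 67.6 %
here although truncation would print 67.5 %.

# The synthetic corpus generator

Corpus-scale recall against an era-matched database snapshot cannot be
reproduced at desk scale, so the package substitutes a generator whose
corpora exercise every branch of the matcher under controlled conditions.
`generateSyntheticCorpus()` builds random gene models (1–4 exons of
120–600 bp, introns of 80–2000 bp, UTRs of 30–200 bp — typical scales for
compact human genes), plants records on them, renders each variant in a
sampled notation, and assembles one document per gene, with spans tracked
for the gold standard.

The defaults encode the observed composition of published SNP mentions:
54 % of mentions are protein-level (slightly more than half, as observed
in curated corpora), and the nucleotide-level notation mixture is
dominated by unprefixed legacy forms (40 % legacy, 20 % genomic, 8 % IVS,
32 % HGVS-prefixed), reflecting that explicit prefixes and IVS forms are
minorities in practice. A fifth of variants are additionally cited by rs
identifier. Corruption operations reproduce the documented error taxonomy
— initiator-Met offsets, Signal-feature offsets, opposite-strand storage,
flipped directionality, digit-permuted rs citations — plus an *unmodeled*
+52 offset that no annotation explains, which must yield `NO_MATCH` and
never a wrong identifier.

Records are drawn by rejection so that every mention validates against
exactly its generating record and decoys collide with nothing; identical
surfaces are kept unique per document (duplicated descriptions are
extracted once per document anyway). Generation is deterministic given
the seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: imperfect gene recognition (gene ids are an
input by design), natural-language variability beyond the documented
surface forms, annotation drift between database versions (start codons
moving between releases), mentions of variants absent from the store, and
full-text phenomena such as tables or hyphenation. The 100 % figures on
clean synthetic corpora are a soundness check of the machinery, not an
estimate of corpus performance.

# Problem sizes and runtime choices

The shipped tests use sizes chosen to make the properties sharp but the
suite quick: the round-trip identity runs over roughly 10^4 triples, the
end-to-end recovery corpora contain 125 genes × 4 variants (≥ 500
mentions) for the headline checks and 10–40 genes for the per-corruption
checks, and the base-by-base oracle comparison samples 250 positions per
model across plus- and minus-strand layouts.

# Known limitations

* Positions are validated against gene models only; there is no
  sequence-level validation of the wild-type base or residue (no FASTA
  input), so a mention with a wrong wild-type symbol but correct position
  and allele set can still match.
* The HGVS grammar is limited to substitutions; duplications, indels and
  complex variants are out of scope, and the `r.` RNA scheme is parsed
  but never matched.
* Records with no gene link (far-promoter variants) are not retrieved,
  since candidates are pooled by gene association.
* The rs-consistency check needs at least one co-mentioned variant
  description; a lone mistyped rs citation is undetectable.
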