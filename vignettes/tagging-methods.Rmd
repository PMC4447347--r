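---
title: "Content-derived gene identifiers and their stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Content-derived gene identifiers and their stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmertag)
```

## The model

A gene's identifier is derived from its own sequence and the k-mer
composition of the catalog it sits in. Writing $C_k(s)$ for the set of
length-$k$ substrings of a sequence $s$ and
$f(t, S) = |\{\, s \in S : t \in C_k(s) \,\}|$ for the number of catalog
sequences containing the k-mer $t$ (a presence count — repeats within one
sequence count once), the tag is

$$u_k(s, S) \;=\; \min \{\, t \in C_k(s) \;:\; f(t, S) \text{ minimal} \,\},$$

the bytewise-lexicographically minimal k-mer among the least-frequent
k-mers of $s$. Most genes have many k-mers unique to them
($f = 1$); the tag is then simply the alphabetically first of those. The
identifier appends a collision suffix, always present: `ARNDCEQGH-1`.

The scheme trades the perfect sensitivity of a cryptographic digest for
locality: a digest changes under any edit, whereas this tag survives every
edit that (a) misses the tag's own locus, (b) creates no smaller
least-frequent k-mer, and (c) does not duplicate the tag k-mer elsewhere in
the catalog. The test suite checks each of those three change conditions on
constructed fixtures, and the merge/split behaviour: concatenating two
genes yields the smaller of their tags unless a junction-spanning k-mer
wins, and splitting leaves the old tag on one part unless the tag spanned
the cut.

## Parameters that matter

* **`k`** (residues; default 9). On the 20-letter peptide alphabet a 9-mer
  has $20^9 \approx 5\times 10^{11}$ possibilities, so almost every gene
  owns a unique 9-mer and the choice of $k$ barely matters — the package's
  k-sweep reproduces this insensitivity across $k = 8..50$. Very small $k$
  makes k-mers common to many genes and tags unstable; $k$ longer than a
  gene collapses the candidate set to the whole sequence (below).
* **Peptide vs nucleotide input.** The algorithm is alphabet-blind and no
  residue validation is performed. Peptides are the natural choice: tags on
  translated sequence are stable across synonymous codon changes and UTR or
  intron edits, and the larger alphabet keeps identifiers short.

## Normalization and degenerate inputs

Sequences are uppercased, whitespace-stripped, and one terminal stop `*` is
removed, so a CDS translated with its stop tags identically to one without;
nothing else is rewritten — internal `*`, `X`, `U` and ambiguity letters
are ordinary symbols. The mathematical candidate set is empty when
$|s| < k$; the package instead defines it as $\{s\}$ so every gene is
tagged (a total function was preferred over dropping records). Empty
sequences raise an error at the library level; the command-line layer skips
them with a counted warning, strictness in the API and robustness at the
shell. Lexicographic comparison is bytewise on uppercased residues —
deterministic and locale-independent. Collision suffixes are numbered
1-based in catalog (input-file) order: reproducible given identical input,
and documented because it is the single order-sensitive component of the
output (permuting the catalog can renumber suffixes but never changes a
tag k-mer).

## Representative proteins and comparisons

For Ensembl-style peptide FASTA with several proteins per gene, one
representative is selected per gene: the record with the bytewise-smallest
protein accession (numeric order for zero-padded accession schemes, with no
vendor-specific parsing). Version suffixes are kept during selection.

Build-vs-build reports count, per compared build of $n$ genes: common full
identifiers (suffix included, since that is what users see; a flag exposes
k-mer-only comparison), common gene and protein accessions (version
suffixes stripped by default, because stable accessions persist while
versions increment), and identical sequences. "Identical sequences" is
counted per gene of the compared build, by membership of its representative
sequence in the reference build's representative set — this makes the
denominator the compared build's gene count, the same denominator used for
every other fraction; the distinct-sequence-intersection alternative is
reported by the optional Ensembl reproduction script since the convention
is genuinely ambiguous. Within one build, `catalog_summary()` reports the
number of distinct peptides and the tag collisions among them — distinct
sequences minus distinct chosen k-mers, i.e. how many distinct peptides
could not be separated by any least-frequent k-mer.

## The synthetic generator

`random_catalog()` draws i.i.d. uniform residues with lengths from a
truncated normal (default 300 ± 75 residues, 20-letter alphabet — the
scale of a typical eukaryotic representative-peptide catalog).
`mutate_build()` turns a catalog into a successor build by applying, in a
fixed order from one seeded RNG stream: gene loss, gene gain, pairwise
merges (plain concatenation, no linker, so the junction caveat is directly
testable), splits at a uniform interior point, then per-residue
substitutions (always to a different symbol) and geometric-length indels.
Every event is logged with gene ids and positions so tests can condition on
whether a mutation touched a tag's locus. The default rates — substitution
0.002 and indel 0.0005 per residue, gain/loss 0.01 and merge/split 0.005
per gene — are gentle, deliberately arbitrary stand-ins for adjacent-build
churn in a maturing annotation project. At these rates a 300-residue gene
keeps a bit-identical sequence with probability
$(1 - 0.0025)^{300} \approx 0.47$, while its tag survives far more often;
the qualitative ordering (common tags ≥ identical sequences) is asserted
over 20 seeds.

What the generator does *not* emulate: biologically structured mutation
(codon bias, domains), repeat families with near-identical copies, and
assembly-scale rearrangements. Passing tests therefore demonstrate the
scheme's combinatorial behaviour under point-like churn, not its
performance on highly repetitive real annotations, where genes with no
unique k-mer are known to collide (repeat masking before annotation, or a
flanking-DNA fallback, are the usual remedies and are out of scope here).

## Problem sizes and numerical choices

The acceptance computation uses a 1,000-gene reference build and its
mutated successor, with the k-sweep over $k = 8..50$; unit and property
tests use catalogs of 1–80 genes, sizes at which an independent brute-force
oracle (explicit enumeration and substring counting) can verify every
assignment exactly, including suffix numbering, on 500 random catalogs.
Ties everywhere are broken deterministically (bytewise order; catalog order
for suffixes), so all results are exactly reproducible from the seeds.

## Known limitations

* Collision suffixes depend on catalog order; pipelines that reorder their
  FASTA between builds can see `X-1` and `X-2` swap even though both k-mers
  persist. The k-mer-only comparison flag quantifies this.
* Tags are only as stable as sequence content: exon-level changes to a gene
  model usually change its tag, and that is by design — the identifier
  tracks content, not genomic position.
* Bytewise "smallest accession" matches numeric order only for fixed-width
  accession schemes; mixed-width schemes would need a numeric comparator.
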