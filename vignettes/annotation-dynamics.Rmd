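---
title: "Tracking transcript biotype dynamics across GENCODE releases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking transcript biotype dynamics across GENCODE releases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annochron)
```

## The problem

GENCODE is the reference catalog of human gene and transcript annotation.
It is not a static resource: between 2008 and 2015 it went through 28 freezes
(V1–V24, including the sub-releases 2a, 2b, 3b, 3c and 3d; V3a was never
published), and with every freeze transcripts were added, deleted, renamed,
or moved between *biotypes* — the functional categories such as
`protein_coding`, `lincRNA` or `processed_pseudogene`. For anyone who
annotated their data against one freeze and compares against another, this
churn matters: a transcript can be a protein-coding gene in one release and a
long noncoding RNA (lncRNA) two releases later.

`annochron` turns this longitudinal comparison into a reusable pipeline. It
reads a chronological series of GTF releases, harmonizes transcript
identifiers across them, builds a transcript × release matrix of biotype
codes, and derives the dynamics statistics: per-release additions and
deletions, biotype transitions, annotation consistency, "moonlighting"
protein-coding/lncRNA identities, biotype-set stability, exon-union genome
coverage, and the overlap of deleted genes with an HGNC symbol set.

## The compendium model

The central object is the **compendium**: a matrix $C$ with one row per
transcript, one column per release, and entries

$$
C_{t,v} \in \{0, 1, \dots, 72, \dots\},
$$

where a nonzero code identifies the biotype of transcript $t$ in release $v$
and $0$ is the *NA state*: the transcript is absent from that release.
The 72 historical biotype names ship with the package
(`biotype_registry()`), each with a fixed integer code; raw attribute strings
are folded into canonical names (lower case, separators to spaces, synonym
resolution) before coding, and names outside the catalog are auto-registered
with codes from 73 upward. Two historical labels, "ig gene" (11) and
"IG gene" (12), differ only by case; canonicalization resolves every raw
spelling to code 11 and code 12 remains a registry entry only.

All statistics are then matrix scans:

* **additions/deletions** at a release pair $(v, v{+}1)$ are the rows moving
  $0 \to$ nonzero and nonzero $\to 0$;
* a **transition** is a change of biotype between consecutive observed
  states;
* a transcript is **consistent** (strict mode) when it is present in every
  release under a single code, or (lenient mode) when it has a single
  distinct observed code;
* class-level statistics group codes into four categories — lncRNA,
  protein coding, others, NA — where the lncRNA class is the 23-sub-biotype
  umbrella (lincRNA, antisense, sense intronic/overlapping, processed
  transcript, retained intron, TEC, the pseudogene subtypes, and the other
  historical noncoding labels). A stricter membership that drops the
  pseudogene subtypes, misc RNA and TEC is available via
  `biotype_class_map(strict = TRUE)` for users who want a conservative
  lncRNA definition.

## Identifier harmonization

A transcript must be one row of the matrix no matter how a release spells
its identifier. Three mechanisms are applied, in order:

1. **Version suffixes** (`ENST00000413529.2` vs `.3`) are stripped; tracking
   across releases requires suffix-insensitive identity. This happens at the
   start of normalization rather than at matrix keying — the result is the
   same, and it lets the identifier map work in unsuffixed coordinates
   throughout.
2. **Pseudo-autosomal duplicates.** The X/Y pseudo-autosomal regions
   historically carried duplicate identifiers (`ENSTR`/`ENSTRR` prefixes,
   later `_PAR_Y` suffixes). These are rewritten to the canonical `ENST0`
   accession; exact duplicates on (id, biotype) are then collapsed, and a
   twin carrying a *different* biotype is kept under the canonical id and
   logged as a conflict. The pattern set is configurable
   (`default_par_patterns()`).
3. **Havana/Ensembl reconciliation.** Early releases identified transcripts
   by Havana (`OTTHUMT`) *or* Ensembl (`ENST`) accessions; later releases
   carry both on one record. Every observed `OTTHUMT` id is classified into
   one of four cases: one lifetime partner (`OTT_1TO1`, mapped globally),
   several partners within one release (`OTT_1TON_SAME_VERSION`, duplicated
   under each partner with the biotype kept), different single partners in
   different releases (`OTT_1TON_CROSS_VERSION`, mapped per release), or no
   partner anywhere (`OTT_UNMAPPED`, kept as-is). Partners are detected
   primarily from dual-identifier record lines; a same-release pair of
   records sharing biotype and exon span set is accepted as a structural
   partner, covering series where the dual attribute is absent.

Two corners of the one-to-many cases are not determined by the definitions
above and are resolved as package design choices: a same-version
one-to-many id observed in a release with *no* partners maps to the union
of partners ever observed, and a cross-version id in a partnerless release
maps to the chronologically nearest observed partner (the earlier release
winning ties). Both choices are deterministic and recorded in the id map,
which serializes as a four-column TSV (`raw_id`, release or `ALL`,
`canonical_id`, case).

When normalization leaves two records with the same (id, release) but
different biotypes, the record from the HAVANA source stream wins (manual
annotation), else the first seen; every such conflict is logged on the
compendium object.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `na_mode` | `IGNORE_NA` | Whether absence participates in transition counts. `IGNORE_NA` counts changes between consecutive *observed* states, so deletion followed by identical re-annotation is not a switch; `NA_AS_STATE` scans the full sequence (leading/trailing absence excluded). The default reflects that additions/deletions are already censused separately, so absence is not itself a switch; both modes are exposed because either convention is defensible. |
| consistency mode | both reported | `strict` requires presence in all releases with one code; `lenient` only a single observed code. Both are always reported side by side. |
| lncRNA class | 23-member | See above; `strict = TRUE` for the conservative membership. |
| PAR patterns | `ENSTRR`, `ENSTR`, `_PAR_Y` | Regex/replacement pairs, first match wins. |
| coverage denominator | whole sizes table | The transcribed fraction divides the exon-union length by the *total* length of the supplied `chrom.sizes` table; chromosomes with zero coverage stay in the denominator. Whether unplaced scaffolds count is controlled by what the user puts in the sizes file. |

## The synthetic corpus generator

Real release series are gigabytes of downloads, so the package ships a
generator (`churn_model()` + `generate_corpus()`) that emulates the
*structural* features the pipeline must survive:

* per-release transcript additions (default 4 % of current size) and
  permanent deletions (default 1.5 % per transcript per release), matching
  the few-percent churn of the real series;
* biotype switching driven by a row-stochastic transition matrix (default:
  stay probability 0.97, uniform otherwise) over a realistic biotype pool
  (about half protein coding);
* identifier duality: before release `dual_from` (default 3) a configurable
  fraction of transcripts appear under `OTTHUMT`-only identifiers; from
  `dual_from` on, records carry `ENST` ids with the Havana id as a companion
  attribute, and version suffixes on the main id;
* planted one-to-many identifier cases (same-version and cross-version),
  pseudo-autosomal duplicate pairs, a small fraction of never-mapped
  `OTTHUMT`-only transcripts, and mid-series gene renames;
* dialect drift: the first release is emitted exon-only, like the first
  GENCODE freeze;
* a toy genome of three 1 Mb chromosomes with 1–5 random exons per
  transcript.

Default sizes are 2,000 initial transcripts over 8 releases — large enough
that every statistic is exercised on thousands of rows, small enough that a
20-seed property run finishes in minutes. The random stream is partitioned
per release, so extending a corpus with more releases never perturbs the
earlier ones.

Alongside the GTF files the generator emits a **ground-truth ledger**: the
true code matrix plus every summary statistic, computed by naive per-row
scans and boolean-mask interval unions — deliberately independent of the
vectorized implementations in the package. `verify_against_ledger()`
compares a pipeline run against the ledger cell-for-cell and names the first
mismatch. The test suite runs this comparison across many seeds, checks the
conservation law $n_{v+1} = n_v + \text{added} - \text{deleted}$ on every
pair, and checks the interval union against the mask oracle on random
1,000-interval fixtures.

What passing these tests shows — and what it does not: the synthetic corpus
covers identifier duality, churn, class switching and dialect drift, but not
everything real files throw at a parser (malformed attribute quoting,
assembly changes between GRCh37 and GRCh38, attribute keys outside the
configured fallback lists, biotype spellings outside the registry and its
synonyms). Those appear in real runs as parse errors, auto-registered
biotypes, or logged conflicts rather than silent miscounts.

## Numerical and degenerate-input choices

* Exon coordinates are 1-based inclusive; the union of `[a,b]` and
  `[b+1,c]` has length `c − a + 1`. Unions are computed with
  `IRanges::reduce()`, strand-agnostic, overlap counted once.
* An empty GTF file, a missing biotype attribute, or a record without exons
  is an error naming the file and line, not a silent skip.
* Within-file duplicate records with identical (id, biotype) collapse
  silently but are counted in the parse report; conflicting duplicates keep
  the first occurrence and warn.
* A single-release series yields an empty delta list but valid totals.
* Transition counting on an all-absent trajectory cannot occur: the matrix
  has no all-zero rows by construction.

## Scale of the shipped checks

The test suite and the acceptance script run entirely on synthetic corpora:
twenty seeded series at 2,000 × 8 for the ledger property, a 500 × 28 series
for the full-catalog end-to-end run, and 1,000-interval fixtures for the
coverage oracle. These sizes are the package's chosen balance between
coverage and turnaround; all statistics are linear in cells, and the same
code path handles the real series (about 250,000 rows × 28 releases) when
the archived GTF files are supplied. A run on the real series is configured
exactly like the synthetic one — a YAML file listing the 28 paths and labels
— and the run report records which setting combination (NA mode, class map,
conflict policies) produced the numbers, since several published headline
counts are sensitive to exactly these conventions.

## A worked example

```{r example, eval = FALSE}
library(annochron)

model <- churn_model(n_initial = 500, n_releases = 8, seed = 1)
corpus <- generate_corpus(model, tempdir())

sizes <- read_chrom_sizes(corpus$sizes_path)
res <- analyze_corpus(corpus$paths, corpus$labels,
                      catalog = corpus$catalog, sizes = sizes)

glance(res$compendium)        # corpus-level summary
glance(res$census)            # mean/max additions and deletions
res$consistency               # strict and lenient consistency
res$moonlighting$summary      # protein-coding/lncRNA overlap
verify_against_ledger(res, corpus$ledger)$pass

plot_growth(res$growth)
plot_presence(res$compendium)
plot_sankey(res$sankey_class)
```

## Known limitations

* Gene-level (ENSG/OTTHUMG) reconciliation is out of scope; gene identity in
  the HGNC comparison is by symbol, case-sensitive, without alias
  resolution.
* Exon-level structural diffing between versions of one transcript is not
  modeled; exon spans are carried only for coverage and partner detection.
* The coverage module does not model intron or whole-gene-span variants, and
  the choice of assembly denominator per release is the user's (via the
  sizes files).
* Sankey output is a nodes/links export; the shipped `plot_sankey()` draws a
  stacked composition overview, not ribboned flows.
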