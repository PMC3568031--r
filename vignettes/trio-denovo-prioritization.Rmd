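---
title: "Prioritizing de novo mutations in trio exome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing de novo mutations in trio exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trionovo)
```

## The problem and the model

Sporadic, severe, early-onset disorders — alternating hemiplegia of
childhood (AHC) is the motivating example — are frequently caused by
heterozygous *de novo* mutations: variants present in the affected child
and absent from both healthy parents. With a handful of unrelated
probands, no linkage information and hundreds of thousands of called
variants per exome, the discovery strategy is a filter cascade followed by
cross-proband recurrence and family-based validation:

1. **Novelty** — discard variants registered in a known-polymorphism
   database (a dbSNP-style table). A causal de novo mutation for a rare
   sporadic disease is not expected to be a catalogued polymorphism.
2. **Consequence** — keep protein-altering and splice-site classes
   (missense, splice acceptor/donor, frameshift and in-frame indels; the
   *NS/SS* set), discarding synonymous and non-coding calls.
3. **Expression** — keep variants in genes expressed in the affected
   tissue (here, a brain-expressed gene set).
4. **Recurrence** — look for sharing across unrelated probands, at two
   granularities: the identical variant recurring, and the same *gene* hit
   by possibly different variants in different probands.
5. **Validation** — re-sequence candidates (modelled by a confirmation
   oracle), screen a healthy control cohort, and type the parents:
   candidates that fail confirmation, occur in any control, or were
   transmitted by a parent in every informative carrier trio are excluded.

Everything upstream of the cascade — alignment, variant calling,
consequence annotation — is taken as given input; the package consumes
annotated variant tables (VCF or a fixed TSV dialect), not reads.

## Known-variant matching: position-only versus allele-aware

Variant identity here is always the 4-tuple (chromosome, position, ref,
alt). The novelty filter, however, supports two matching semantics because
the difference has historically mattered: a collation that matches on
chromosome and position *only* will call a query "known" whenever **any**
allele at that site has been registered. The canonical failure is
ATP1A3 D801N (chr19:42474557 G>A): the same position carries the registered
rapid-onset dystonia-parkinsonism allele D801Y (G>T), so a position-only
collation silently removes D801N, which is in fact novel. The
`allele_aware` mode (the default) requires the full 4-tuple to match.
`position_only` is retained as an explicit flag so that the failure mode —
and the two mechanisms that rescue its victims — can be reproduced and
tested:

- **Gene refocus** (`gene_refocus()`, or `refocus_genes=` in
  `run_pipeline()`): once a gene is implicated by the surviving variants,
  re-examine *all* of its consequence-passing variants in the pre-novelty
  data, database-registered or not. This is only possible if pre-filter
  data are retained, which the pipeline does by default.
- **Confirmation sequencing** of the implicated gene in all probands.

A structural invariant, enforced in the tests: the allele-aware survivor
set always contains the position-only survivor set, and the difference is
exactly the variants that share a position (but not an allele) with a
database record.

## Recurrence and the candidate definition

`shared_variants()` reports both granularities. The default candidate
definition in `run_pipeline()` is **gene-level** sharing with
`min_carriers = 4`: any variant of a gene carried by at least 4 probands
becomes a candidate. Four is half of the 8-proband discovery cohort the
package's fixture models, and it is the smallest sharing that cohort's
study pursued (a gene with 4 carriers of 4 different variants); the
threshold is exposed as a parameter, not hard-coded. Gene-level sharing
counts distinct probands, not variants, so a gene with one variant in six
probands and a gene with four variants in four probands are both flagged.

Prevalence is reported as carriers over probands, with the percentage
rounded half-up to an integer (the convention under which 19/82 prints as
23%).

## Trio classification

`classify_trio()` is deterministic and total over the finite
genotype/availability space (the tests compare it to a brute-force
enumeration): a carrier proband with both parents observed homozygous
reference is `de_novo`; an observed carrier parent gives the corresponding
`inherited_*` status and dominates an uninformative other parent; a
carrier proband whose needed parent is unavailable or has a failed call is
`unknown_parent`. Two conventions matter and are deliberate:

- An *absent record* for an individual is read as homozygous reference —
  the exome-table convention that only non-reference calls are
  materialized. An explicit `missing` call for the proband, by contrast,
  is an error: classification never proceeds from a failed proband call.
- A variant inherited in one carrier but de novo in another is retained
  (the de novo observation dominates); a candidate whose carriers are all
  uninformative is retained but flagged **unvalidated** rather than
  discarded — in the modelled study, one patient's parents declined
  testing, and her mutation remained a candidate through the other,
  confirmed-de-novo carriers. Candidates mixing inherited and
  uninformative carriers (no de novo observation) are likewise kept
  unvalidated rather than excluded: the exclusion rule demands inheritance
  in *every informative* carrier.
- Control exclusion is "any carrier": presence in even 2 of 96 healthy
  controls disqualifies a fully penetrant dominant candidate.

## Substitution impact: Grantham distance and conservation

External trained classifiers (PolyPhen-2 style) are not reimplemented;
impact is scored by two transparent quantities, used ordinally — the
package asserts no pathogenic/benign cut-off.

**Grantham distance.** The physicochemical dissimilarity of two residues,
from side-chain composition $c$, polarity $p$ and molecular volume $v$:

$$D_{ij} = \rho\,\sqrt{\alpha (c_i-c_j)^2 + \beta (p_i-p_j)^2 + \gamma (v_i-v_j)^2}$$

with $\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$ and $\rho$
normalizing the mean of the 190 pairwise distances to 100
($\rho \approx 50.79$). The scale runs from 5 (Leu/Ile) to 215 (Cys/Trp).
The package computes from this model in full precision and rounds only for
reporting. One numerical caveat is documented rather than hidden: the
historical integer table reprinted throughout the literature is internally
inconsistent with its own formula at the unit level (no single $\rho$
reproduces both of its entries Glu–Lys = 56 and Cys–Trp = 215; the model
yields 57 and 215). The test suite therefore checks the property values
exactly against the published amino-acid indices, checks canonical
benchmark entries exactly, and checks all 190 pairs to within the printed
table's unit rounding.

**Conservation.** Given an aligned orthologue/isoform panel (aligned
FASTA), `conservation_fraction()` returns the fraction of non-gap rows
matching the *reference* (human) residue at the queried residue number.
The reference residue anchors the comparison; rows gapped at the column
leave the denominator, and a column where every non-reference row is
gapped is an error, not a score. Curated cross-species panels are not
shippable here, so the packaged alignments are synthetic
(`synthetic_homolog_alignment()`, labelled as such); real use loads an
orthologue alignment with `read_homolog_alignment()`.

Ranking (`rank_candidates()`) orders by confirmed de novo carriers, then
total carriers, then conservation, then Grantham distance, with genomic
coordinate as the deterministic tie-break.

## The synthetic cohort generator

`simulate_cohort()` emits a complete input bundle — variant tables for
probands and parents, pedigree, known-variant database, control
genotypes, confirmation oracle — with a truth sidecar labelling every
variant:

- `known_background`: registered in the database, transmitted by one
  parent;
- `novel_benign_inherited`: unregistered, transmitted by one parent;
- `sequencing_artifact`: unregistered, de-novo-looking (both parents
  reference), failing the confirmation oracle;
- `planted_de_novo`: the pathogenic signal — absent from database,
  parents and controls, shared by a configurable number of probands,
  confirmed by the oracle.

Defaults model a desk-scale version of an 8-trio exome study: 5,000
variants per proband (a stand-in for the ~200,000 a real exome yields,
preserving the cascade's selectivity profile at test speed), 80% of them
database-registered, 35% of novel variants protein-altering/splice-site,
30% of variants in brain-expressed genes — chosen once so the expected
brain-expressed novel NS/SS count per proband is ≈105, inside the
77–129 per-patient range reported for such cascades — one planted variant
shared by 5 of 8 probands (the sharing level of the modelled discovery),
an artifact rate of 0.002, and 96 controls. Positions are drawn without
replacement from a synthetic exome coordinate space; genes come from a
synthetic list with a flagged brain-expressed subset. Generation is fully
reproducible from the seed.

What the simulator does *not* model — and therefore what passing tests do
not show about real data: genotyping error and missingness, parental
mosaicism and non-paternity, population allele-frequency structure
(novelty is binary registered/unregistered, as in the modelled pipeline),
mutation-rate heterogeneity, indel left-alignment ambiguity (matching is
exact at this scale), and shared artifacts (simulated artifacts are
private to one proband; the shared-artifact path is exercised by the
fixture's CNTN4-like decoy instead).

`plant_position_collision()` adds a database record at a planted variant's
site with a different allele, recreating the D801N/D801Y configuration:
under `position_only` the cascade misses the planted variant, under
`allele_aware` or after `gene_refocus` it is found.

## The in-paper fixture

`fixture_paper_cohort()` transcribes the study facts the pipeline needs:
ten probands, four ATP1A3 mutations with their published chromosome-19
coordinates and carrier assignments (E815K in II-1/III-1/IV-1 plus the two
extension patients IX-1/X-1; D801N in VI-1/VII-1/VIII-1; G755C in I-1;
C927Y in V-1), the six-carrier CNTN4 call that fails confirmation, the
four inherited novel SYNE1 variants plus fifteen registered SYNE1
substitutions (a SYNE1 refocus sees 19 distinct non-synonymous variants,
per-sample counts 10/10/8/10/9/8/10/9), the D801Y collision record, 96
controls (2/2/2 carriers of three SYNE1 variants, none of any ATP1A3
mutation), trios with IX-1's parents unavailable, and the clinical
phenotype table. Coordinates for the SYNE1/CNTN4 decoys are synthetic
placeholders (only the chromosome-19 positions are published);
per-sample assignment of the registered SYNE1 variants is synthetic in the
same sense, constrained to reproduce the published per-sample totals.

Two source inconsistencies are worth knowing about. The study's published
materials disagree on which of two patients carries G755C versus E815K
(three mutually inconsistent per-patient assignments appear across its
tables, narrative and figure legends); the fixture follows the main
variant and clinical tables, and all aggregate counts (5/3/1/1 carriers
for E815K/D801N/G755C/C927Y) are identical under every reading. Likewise
the published materials disagree on whether patient IX-1's parents were
genotyped; the fixture treats
them as unavailable, so IX-1's E815K is classified `unknown_parent` and the
mutation stays validated through its other, de novo carriers. The fixture
self-checks the aggregate carrier counts at construction.

```{r fixture}
fx <- fixture_paper_cohort()
r8 <- run_pipeline(fx$cohort,
                   fx$trios[fx$trios$proband_id %in% fx$exome_probands, ],
                   fx$known_db, fx$gene_set, fx$controls, fx$oracle)
r10 <- extend_cohort(r8, fx$extension,
                     fx$trios[fx$trios$proband_id %in% c("IX-1", "X-1"), ])
r10
```

## Numerical and design choices

- **Coordinates** are 1-based inclusive (VCF convention); no liftover.
- **Variant identity** excludes annotations; multi-allelic VCF rows are
  split per alternate allele before any filtering; when a source supplies
  several annotations for one variant, the most severe consequence is
  kept, using the field-standard severity ranking
  (splice_acceptor > splice_donor > frameshift_indel > missense >
  inframe_indel > synonymous > other).
- **Indels** pass the same novelty/consequence/expression filters as SNVs
  and are tallied separately in the cascade report; matching is exact
  (no left-normalization) at this scale.
- **Cohort totals** are reported twice, as per-sample sums and as unique
  counts (each distinct variant key or gene once), because the two differ
  whenever variants recur across samples and only the unique reading is
  internally consistent.
- **Missing gene symbols** fail the expression filter (conservative,
  deterministic).
- **Record conservation**: every variant carried by any proband appears
  exactly once in the report, either as a surviving candidate or in the
  removal log with a reason (`registered_known`, `consequence_filtered`,
  `not_brain_expressed`, `below_min_carriers`, `confirmation_failed`,
  `present_in_controls`, `inherited_in_all_carriers`).
- An empty candidate set is a successful result, distinguished from
  errors.

## Problem sizes used by the test suite

The packaged checks run the fixture (milliseconds) and seeded simulations
at 8 trios × ~5,000 variants per proband; the end-to-end recovery property
(planted variant recovered exactly, nothing else surviving) is exercised
across 20 seeds, and distributional checks on cascade counts use binomial
3-standard-error bands. These sizes are the package's own choice of a
desk-scale model that preserves the cascade's selectivity profile.

## Limitations

The pipeline assumes fully penetrant, monogenic, dominant de novo
causation; it will not find recessive, mosaic or oligogenic signals. The
novelty filter is binary and only as good as the supplied database —
which is precisely the property the position-only/allele-aware machinery
is built to probe. Consequence annotation is trusted input. The
confirmation oracle abstracts wet-lab validation as a perfect lookup;
real Sanger follow-up has its own failure modes. No statistical
enrichment test for recurrence is provided (none is needed at this cohort
scale, and carrier counts are reported directly).
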