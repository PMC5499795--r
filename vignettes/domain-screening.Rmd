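---
title: "Screening proteomes for functional classes by domain prediction"
author: "DomainSifter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for functional classes by domain prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DomainSifter)
```

## The problem and the model

Many protein functional classes — RNA-binding proteins (RBPs) being the
motivating example — are defined operationally by the conserved domains their
members carry: RRM, KH and cold-shock domains for RBPs, kinase domains for
kinases, and so on. Given a set of query protein sequences and a set of
keywords naming the class of interest, DomainSifter screens the queries in
five stages:

1. **Reference domain selection.** A domain annotation table (identifier,
   accession, short name, description, length, optional consensus sequence
   and GO annotations) is searched with the keywords. An entry is selected
   when at least one term matches one of its annotation fields; a multi-word
   term must have *all* of its words inside a single field. Matching is
   case-insensitive substring matching, so the term `RNA-bind` selects
   entries annotated "RNA-binding" — deliberately permissive, because the
   reference set is subsequently what defines the class.
2. **Domain prediction.** Predicted domain occurrences on the queries come
   from external profile search engines, whose tabular outputs are parsed
   (the extended BLAST-tabular dialect with `positives`/`gaps` columns, and
   the InterProScan-style TSV layout), or from the built-in ungapped profile
   scanner when no external engine is available.
3. **Candidate filtering.** Each hit is reduced to four statistics and gated
   by cut-offs; proteins with at least one passing hit on a reference domain
   are the candidates.
4. **Feature scoring.** Each retained site is compared with its reference
   consensus fragment across four feature categories and the per-feature
   scores are combined into a single 0–1 score with empirical P-values.
5. **Assessment.** When truth labels exist, performance is summarized with
   the standard binary metrics, ROC/AUC, and threshold-sweep cut-off
   optimization.

## Hit statistics and the default cut-offs

For a hit spanning subject positions $s_{start}..s_{end}$ on a reference
domain of length $L$, with $n_{pos}$ positive-scoring and $n_{id}$ identical
aligned residues:

$$\mathrm{coverage} = 100\,\frac{s_{end}-s_{start}+1}{L},\qquad
\mathrm{similarity} = 100\,\frac{n_{pos}}{L},\qquad
\mathrm{identity} = 100\,\frac{n_{id}}{L}.$$

The denominator is the **reference domain length**, not the alignment
length: a short, locally perfect match over a fifth of a domain is weak
evidence for the domain's presence, and dividing by $L$ encodes that. The
gap fraction alone is a property of the alignment and uses the alignment
length as denominator. Well-characterized *E. coli* RBPs illustrate the
scale of these statistics:

```{r table2}
ds <- DomainSet(data.frame(
  domain_id = c("csra", "rrm"), accession = c("EX1", "EX2"),
  short_name = c("CsrA", "RRM_RBM7"), description = c("x", "y"),
  length = c(69L, 75L)))
hits <- rbind(
  DomainSifter:::.new_hit_row("CsrA", "rpsblast-like", "csra",
                              1, 58, 1, 58, 58, 34, 50, 0, 1e-20, 80),
  DomainSifter:::.new_hit_row("Hfq", "rpsblast-like", "rrm",
                              1, 31, 1, 31, 31, 13, 19, 0, 1e-5, 40))
st <- hitData(computeHitStats(new("HitTable", hits = hits), ds))
round(st[, c("coverage_pct", "similarity_pct", "identity_pct")], 2)
```

The default combined filter is **coverage ≥ 39 AND similarity ≥ 24** (per
cent), the cut-off pair optimized on curated positive/negative training sets
of RBPs versus non-RBPs; minimum identity (optimized value 15%), maximum
E-value (optimized value 0.01) and maximum gap percentage are available but
opt-in, because coverage and similarity were the two most discriminative
parameters and stacking weak filters mostly costs sensitivity. Boundary
values pass (the cut-offs are minima/maxima). Hits from dialects that do not
report residue counts (InterProScan-style) are gated on the remaining
parameters and flagged `partial_stats` rather than discarded — the point of
combining prediction methods is that each recovers proteins the other
misses; a hit whose *coverage* cannot be computed (unknown reference) does
fail an enabled coverage threshold, since coverage is the core parameter.

## Feature scoring

For every candidate hit, the predicted query region and the corresponding
consensus fragment are compared across four categories:

* **Chemical properties** — average mass, isoelectric point (bisection on
  the Henderson–Hasselbalch net charge to $|q| < 10^{-4}$, using the
  packaged EMBOSS-style pKa scale), and count-weighted mean side-chain pKa.
  Each is scored as relative agreement $1 - \min(1, |q - r|/r)$. The pKa and
  mass tables ship as package data files so results are bit-stable across
  environments.
* **Alignment** — global (Needleman–Wunsch/Gotoh) alignment of the primary
  sequences under BLOSUM62 with affine gaps (open −10, extend −0.5; a
  length-$L$ gap costs $open + (L-1)\,extend$), normalized by the reference
  fragment's self-score so identity gives 1; and the same alignment over
  3-state secondary-structure strings (+1 match / 0 mismatch / −1 gap
  position). When no secondary structure is supplied, a simple per-residue
  Chou–Fasman propensity classifier stands in for a real predictor — it is
  a stand-in, labelled as such, adequate only for relative comparisons
  between a region and its consensus.
* **Composition distances** — Euclidean distances between dipeptide,
  tripeptide and physico-chemical composition vectors (four residue groups:
  hydrophobic AVLIMFWP, polar GSTCYNQ, acidic DE, basic KRH, plus group-pair
  transition frequencies), each mapped to $(0, 1]$ by $1/(1+d)$. The mapping
  is not prescribed by theory; $1/(1+d)$ was chosen because it is bounded,
  strictly decreasing and equals 1 exactly at $d = 0$.
* **Site similarity** — the hit's residue identity as a fraction, the one
  per-site similarity measure available from the prediction statistics
  themselves; unavailable (NA) for dialects without residue counts.

Scores are combined as a naive-Bayes posterior with uniform prior,
$\prod s_i / (\prod s_i + \prod(1-s_i))$, after clamping each score to
$[10^{-6}, 1-10^{-6}]$; NA features are skipped. The combination is
symmetric, strictly increasing in each argument, 0.5 when all features are
uninformative, and 1 only for a complete match. Empirical P-values attach to
the sequence-based features only: the null is the same feature recomputed on
composition-preserving shuffles of the query region (default 100 shuffles),
with $p = (1 + \#\{null \ge obs\})/(1 + n)$, never zero and deterministic
given the seed. The chemical properties get no P-values (shuffling preserves
composition, hence mass, pI and pKa exactly), and neither does site
similarity, which comes from the hit statistics rather than the region.

```{r score-example}
doms <- exampleDomainSet()
cons <- consensusOf(doms, "synCSD")
query <- paste0("MKT", cons, "GGS")
hit <- list(query_id = "Q1", domain_id = "synCSD", q_start = 4L,
            q_end = 3L + nchar(cons), s_start = 1L, s_end = nchar(cons),
            identity_pct = 100)
scoreHit(hit, query, doms, control = featureControl(nShuffles = 50))
```

## Assessment

The five metrics follow the conventional equations, with one deliberate
oddity kept for comparability: the F-measure is
$2\,SN\,SP/(SN+SP)$ — the harmonic mean of **sensitivity and specificity**,
not of precision and recall. MCC uses the $TP \cdot TN - FN \cdot FP$
numerator and is defined as 0 when any marginal is empty, as is any metric
with a zero denominator. Reported tables round half-up to two decimals;
full precision is kept internally. (On rounding: a recovery of 129/160 =
0.80625 prints as 0.81 under half-up rounding; sources that truncate would
print 0.80.)

ROC curves sweep the distinct score values from high to low with tied items
crossing together; the AUC is the trapezoidal area, which equals the
Mann–Whitney probability that a random positive outscores a random negative
(the test suite checks this equivalence against an independent rank-sum
oracle). Cut-off optimization sweeps every distinct parameter value as a
candidate threshold and picks the accuracy maximum; the paper-style verbal
criterion ("TPR close to one, FPR close to zero, high ACC") is not a single
formula, so accuracy was chosen as the objective with Youden's J
($TPR - FPR$) and then the less stringent threshold as tie-breaks, and the
full sweep table is returned so users can apply their own criterion.
`residueOverlap` supports interval-level validation: the fraction of
annotated binding residues falling inside predicted domain sites, per
protein and as a cohort sensitivity.

## The internal scanner

The built-in scanner exists so the pipeline runs end-to-end with no
external binaries: profiles are per-position log-odds with additive
pseudocounts ($\lambda = 1$) against a uniform background, scanning is
**ungapped** (gapped hits enter via the external-dialect parsers), and
significance is empirical — the E-value of a window score is the expected
number of at-least-as-good windows in a composition-preserving shuffle of
the query (default 200 shuffles, hits reported at E ≤ 0.01). This avoids
fitting analytic score statistics at desk scale but makes the scanner
unsuitable as a general search engine: no gaps, no composition adjustment,
null resolution limited by the shuffle count.

## The synthetic-data generator

`generateLabeledSet` emulates the class structure the screen is meant to
detect: positives carry exactly one mutated copy of a randomly chosen
domain consensus overwritten at a recorded position; negatives are pure
background. Defaults are 50 positives, 50 negatives, protein lengths uniform
in 150–250 residues, 10% substitution rate, no indels, uniform residue
background. The substitution rate of 0.1 leaves planted copies around 90%
identical to their consensus — clearly detectable but not trivially so; the
uniform background is the simplest null and is all the filtering contracts
need. Indels are single-residue events so truth-table coordinates stay
exact. `emitHitTables` writes the corresponding hit tables in both external
dialects, with statistics recomputed from the realized mutated region
(position-wise comparison, exact for the indel-free default), plus seeded
spurious low-coverage hits.

What the generator does **not** emulate: real domain families have
position-specific conservation, insertions and deletions, non-uniform
residue composition, and homologous (not independently random) negatives.
Passing tests on these fixtures therefore demonstrates the correctness of
the machinery — parsing, statistics, filtering logic, score bounds,
determinism — not the biological error rates of a real screen, which depend
on the domain databases and search engines used.

```{r fixture-run}
fix <- generateLabeledSet(fixtureConfig(nPositive = 10, nNegative = 10,
                                        seed = 7), doms)
out <- runPipeline(fix$sequences, doms, keywords = "RNA-bind",
                   outDir = file.path(tempdir(), "vignette-run"),
                   labels = setNames(fix$truth$label, fix$truth$protein_id),
                   seed = 7, scanShuffles = 100,
                   control = featureControl(seed = 7, nShuffles = 20))
metricsVector(out$metrics$metrics, digits = 2)
```

## Numerical and design choices

* **Alignment gap convention.** A gap of length $L$ costs
  $open + (L-1)\,extend$ (the first gap residue pays the opening penalty).
  The alignment is implemented in-package because the installed aligners use
  a different convention ($open + L\,extend$) and reject empty sequences,
  which the degenerate-input contract here requires; the test suite pins the
  implementation to an independently written memoised-recursion oracle.
  `X` is tolerated and scores 0 against everything.
* **Normalization by reference self-score** bounds the alignment feature in
  $[0,1]$ with 1 at identity; raw scores can be negative, so the normalized
  value clamps at 0.
* **Keyword matching** is case-insensitive substring over each annotation
  field separately; hyphens and underscores are ordinary characters and
  there is no stemming (the canonical class term `RNA-bind` relies on raw
  prefix matching). Plain terms see GO term *names* only; GO identifiers are
  matchable in regex mode. Whether the original behavior was case-sensitive
  or token-based is not documented; case-insensitive substring is the more
  permissive reading and is stated here so results are interpretable.
* **Span-based hits** (InterProScan-style) report no subject coordinates;
  coverage uses the matched query span over the reference length, capped at
  100 so a span overshooting the reference is not rewarded.
* **Scale of the shipped examples.** Test and vignette runs use 10–100
  proteins, three reference domains of 60–70 residues, and 20–200 shuffles
  per empirical null; these sizes make the whole suite reproducible on a
  single CPU in a few minutes while leaving every code path exercised.

## Known limitations

* The Bayesian combination treats features as independent; composition
  distances and alignment scores are correlated, so the combined score is a
  ranking device, not a calibrated probability.
* The built-in secondary-structure predictor is a per-residue propensity
  table; its absolute accuracy is poor and only the relative comparison
  between a region and its consensus fragment is meaningful.
* The internal scanner is ungapped; domains with frequent indels will be
  recovered only via the external-dialect parsers.
* Identifier-based retrieval (fetching sequences or taxonomies from remote
  services) is out of scope: queries are FASTA in, tables out, and the tool
  is fully network-free.
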