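---
title: "Methods: evidence aggregation, ontology propagation and LRT signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence aggregation, ontology propagation and LRT signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdassoc)
```

## The problem

Target identification platforms integrate evidence from genetics portals,
somatic-mutation catalogues, clinical-trial records, pathway analyses,
expression atlases, literature mining and animal models into a single
ranked view of target–disease associations, and annotate drugs with
post-marketing adverse-event signals. `tdassoc` implements that
computational core — validation, ontology propagation, harmonic-sum
scoring, and likelihood-ratio-based pharmacovigilance — as a desk-scale,
fully testable engine operating on synthetic or user-supplied data.

## Evidence model

An evidence string carries a target id (`ENSG` + 11 digits), a disease
CURIE, a data source, one of seven data types, and a source-specific score
payload. Records are validated against the JSON-schema-style document in
`inst/extdata/evidence-schema.json`; the validator interprets the subset of
keywords that contract uses (`required`, `type`, `pattern`, `enum`,
`minimum`/`maximum`). We chose to interpret the schema document rather than
hard-code rules so the contract stays declarative and editable; no R
JSON-schema validator was available in the target environment, and the
interpreter is small and property-tested (randomly generated conforming
records are accepted at 100%).

Deduplication keys on (target, disease, datasource, canonical payload
hash), where "canonical" means recursively key-sorted JSON. Byte-identical
resubmissions collapse; genuinely different payloads (different scores,
different study ids) survive. Invalid records are excluded and itemised,
never repaired.

## Ontology propagation

The disease ontology is a DAG of `is_a` child→parent edges; other OBO
relationship types are deliberately ignored. Evidence asserted at a term is
emitted `direct` there and `indirect` at every ancestor, with three rules:

* propagation stops **at and includes** therapeutic-area nodes — the walk
  never continues above one, even when it starts there;
* a configured generic root term is excluded entirely;
* multi-path reachability is deduplicated per (evidence, ancestor), so a
  diamond-shaped region contributes each record once per node. This is what
  keeps harmonic sums free of double counting.

`ancestors()` is an iterative BFS over parent lists; the test suite checks
it exactly against an independently written recursive-DFS closure on 100
random DAGs (≤ 50 nodes, ≤ 3 parents per node). We treat all ontology
branches uniformly (no disease-vs-phenotype axis special-casing), which is
the simplest defensible reading of a propagation rule stated only in terms
of parents and therapeutic areas.

## Scoring model

Per-evidence scores lie in [0,1]. Four scorers ship, dispatched per data
source, with a pass-through default (clipped `resource_score`):

| scorer | rule | default parameter |
|---|---|---|
| genetics portal | reject if `gwas_pvalue` > cutoff, else `resource_score` | cutoff 5e−8 |
| CRISPR screen | reject if `priority_score` < floor, else `/100` | floor 40 |
| known drug | phase map on `clinical_phase` 0..4 | 0.05, 0.1, 0.2, 0.7, 1.0 |
| pass-through | `resource_score` clipped to [0,1] | — |

Rejection (`NA`) removes the record before aggregation and is counted.
The phase→score map is not printed in the main text of the platform's
literature; the shipped default rises steeply at phases 3–4 (approved or
late-stage drugs are far stronger evidence) and is plain configuration.

Aggregation is a normalized harmonic sum: sort scores descending and
compute $\sum_{i=1}^{\min(n,\mathrm{cap})} s_{(i)}/i^2 \big/
\sum_{i=1}^{\mathrm{cap}} 1/i^2$ with cap = 100. The normalisation constant
is a design choice (the source material states scores are in [0,1] but does
not print the constant): dividing by the cap-term maximum makes the score
reach exactly 1 when cap pieces of perfect evidence exist, and makes the
empty sum 0. Data-source scores are combined into data-type scores and the
overall score by the same reduction applied to weight-multiplied source
scores, i.e. the overall score is computed directly from data-source scores
(not from data-type scores, which are reported alongside). Weights are
multiplied **before** the descending sort, so a down-weighted source can
never displace a strong source from the leading $1/i^2$ slots.

Default weights are 1.0 for genetic association, somatic mutation, known
drug and affected pathway, and 0.2 for RNA expression, literature and
animal model — a deliberately coarse strong/contextual split, fully
overridable per source; the production weight table is release
configuration, not something this package claims to reproduce.

Consequences, all property-tested: scores are bounded in [0,1]; appending
evidence never lowers a raw harmonic sum; association scores at an ancestor
disease dominate every descendant (evidence superset + monotonicity);
ranked output uses the deterministic tie-break (evidence count descending,
then target id, then disease id).

## Pharmacovigilance

Report tables are filtered in a fixed order: reporter-qualification
whitelist (health professionals), drug-role whitelist (suspect drugs),
case-level deduplication keeping the highest report version, and an
editable blacklist of uninformative event terms
(`inst/extdata/event-blacklist.txt`). Counts are over distinct case ids.

For drug $j$ and event $i$, with $n_{ij}$ co-mentions, marginals $n_i, n_j$
and $N$ reports, the one-sided binomial log-likelihood-ratio is
$$\mathrm{LLR} = n_{ij}\log\frac{n_{ij}}{E_{ij}} +
(n_j-n_{ij})\log\frac{n_j-n_{ij}}{n_j-E_{ij}},\qquad E_{ij}=\frac{n_i n_j}{N},$$
zero when $n_{ij}\le E_{ij}$ (under-reporting is not a signal) and with
$0\log 0 := 0$. The source material names the likelihood-ratio test and its
Monte-Carlo critical values without printing a formula; this is the
standard construction from the pharmacovigilance LRT literature it cites.

Critical values: for each drug, `n_sims` null datasets reallocate the
drug's $n_j$ reports across all events multinomially with probabilities
$n_i/N$; the per-dataset maximum LLR over events forms the null sample, and
the critical value is its inverse-ECDF $(1-\alpha)$ quantile (type 1 —
deterministic and monotone in $\alpha$). The maximum-statistic construction
controls the per-drug family-wise false-positive rate at about $\alpha$.
Per-drug child seeds are derived by hashing the drug id into the master
seed, so results do not depend on drug processing order. Defaults
$\alpha = 0.05$, `n_sims` = 1000.

One calibration property is worth stating precisely: because each drug's
own reports are included in the event marginals $n_i$ used both in
$E_{ij}$ and in the null probabilities, the observed statistic is slightly
shrunk relative to the simulated null, and the realised family-wise rate in
a 20-drug world sits near 0.03 rather than 0.05 (with 100+ drugs it
approaches the nominal level; with marginals treated as known truth the
machinery is calibrated at $\alpha$ exactly, which the tests verify
separately). This mild conservatism is inherent to conditioning on
estimated marginals — the "implicit correction" for drug and event
frequency — and is not corrected for, matching the method as described.

## Synthetic data: the stated world

The generators are pure functions of (spec, seed); reruns are
byte-identical, and each emits a coverage manifest the pipeline manifest is
checked against.

* **Ontology**: 30 terms, ≤ 3 parents, 3 therapeutic areas under one
  excluded generic root; acyclic by rank construction; OBO and edge-TSV
  serialisations describe the same graph.
* **Evidence**: 1,000 background records over 20 targets; scores follow
  Beta(2,5) — most evidence weak, a few strong, a realistic shape chosen
  once since no score distribution is published; 2% of records are planted
  schema-invalid, 5% of genetics records fail the p-value cutoff and 30% of
  screen records fall below the priority floor, so every rejection path is
  exercised. One planted association: 50 records at score 0.9 (distinct
  study ids, so deduplication keeps them).
* **Reports**: 50,000 reports over 20 drugs (uniform marginal) and 200
  events (1/rank marginal — spontaneous-report event frequencies are
  heavy-tailed); one planted pair at relative risk 10, injected by
  multiplying the event's probability and renormalising that drug's event
  distribution so report totals stay comparable; 5%/5%/2%/2% of rows
  violate the qualification/role/version/blacklist filter rules.

What a green test does **not** establish: realistic identifier
vocabularies, MedDRA structure, correlated multi-drug reports (each
synthetic report carries one drug and one event), per-source score
formulas beyond the four shipped scorers, or any claim about production
weight values.

## Numerical and degenerate-input choices

* Harmonic sums reject inputs outside [0,1] rather than clipping; clipping
  happens only in the pass-through scorer where payloads are untrusted.
* Empty score vectors give 0; an empty evidence stream gives an empty
  association table; empty contingency counts give an empty signal table.
* A drug seen with a single event in the whole table gets critical value 0
  (degenerate null), not an error.
* The simulated null clamps a drug's simulated event count at the event's
  marginal so the LLR precondition $n_{ij}\le\min(n_i,n_j)$ always holds;
  the clamp is vacuous except for vanishingly rare tail draws.
* Quantile type 1 keeps critical values reproducible across platforms and
  exactly monotone in $\alpha$.
* Run manifests include a wall-clock timestamp; determinism checks compare
  all data artifacts byte-for-byte and the manifest minus that field.

## Limitations

Desk-scale by design: associations are held in memory (data.table), the
OBO parser reads only `[Term]`/`id:`/`name:`/`is_a:` stanzas, and no
attempt is made to reproduce the 20 production ingestion pipelines, their
exact schemas, or release-level counts. The weight table, phase map,
normalisation cap and all thresholds are configuration with documented
defaults, not published constants, except the GWAS p-value cutoff (5e−8)
and the priority-score floor (40).
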