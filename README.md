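# tdassoc

Target–disease association scoring and pharmacovigilance signal detection
for drug-discovery knowledgebases.

Systematic target identification aggregates heterogeneous *evidence
strings* — units of support linking a target (an Ensembl gene) to a disease
(an EFO-style ontology term) through a data source such as a GWAS portal, a
CRISPR fitness screen, clinical-trial records or literature mining — into
ranked target–disease associations. `tdassoc` re-implements that
computational core in R, for methodologists and engineers who want a
transparent, fully testable engine rather than a production web platform:

1. **Evidence validation** — records are checked against a JSON-schema-style
   contract shipped with the package (identifier patterns, the seven data
   types, payload ranges) and deduplicated on (target, disease, source,
   canonical payload hash).
2. **Ontology propagation** — evidence asserted at a disease term is copied
   to every ancestor up to and including its therapeutic area(s), so a
   target associated with Crohn's disease also supports, indirectly, the
   broader inflammatory-bowel-disease term.
3. **Harmonic-sum scoring** — each record is scored in [0,1] by a per-source
   scorer (GWAS evidence requires p ≤ 5×10⁻⁸; CRISPR-screen evidence
   requires a priority score ≥ 40; clinical-phase evidence maps phase → score),
   then aggregated per data source as

   *S* = Σᵢ s₍ᵢ₎ / i² ⁄ Σᵢ₌₁..cap 1/i²  (scores sorted descending, cap = 100),

   and data-source scores are combined into data-type and overall scores by
   the same reduction applied to weight-multiplied source scores. Many
   independent pieces of evidence raise a score with diminishing returns.
4. **Pharmacovigilance** — FAERS-style adverse-event report tables are
   filtered to reliable entries, aggregated into drug×event contingency
   counts over distinct reports, and screened with a one-sided binomial
   likelihood-ratio statistic; per-drug critical values come from a
   Monte-Carlo null that reallocates the drug's reports across events
   multinomially with the background event frequencies, controlling the
   per-drug family-wise false-positive rate at ≈ α.

A synthetic-data module generates ontologies, evidence sets and report
tables with planted associations and planted adverse-event signals, so the
whole pipeline runs and is tested with no external data.

## Worked example

```r
library(tdassoc)

spec <- fixture_spec(seed = 42, evidence = list(n_evidence = 400L),
                     faers = list(n_reports = 20000L, n_drugs = 10L,
                                  n_events = 50L))
dir <- tempfile(); dir.create(dir)
onto <- make_toy_ontology(spec, out_dir = dir)
ev   <- make_evidence_set(spec, onto, path = file.path(dir, "evidence.jsonl"))
rep  <- make_faers_reports(spec, path = file.path(dir, "reports.tsv"))

m <- run_pipeline(list(
  seed = 42,
  evidence = file.path(dir, "evidence.jsonl"),
  ontology = onto$tsv_path,
  therapeutic_areas = onto$therapeutic_areas,
  root_ids = onto$root_id,
  reports = file.path(dir, "reports.tsv"),
  faers = list(alpha = 0.05, n_sims = 500L)),
  out_dir = file.path(dir, "out"))
str(m$counts)
#> $ input               : int 450     <- 400 background + 50 planted records
#> $ valid               : int 441     <- 9 records are deliberately schema-invalid
#> $ score_rejected      : int 20      <- GWAS p-value / priority-score filters
#> $ expanded            : int 3650    <- each record once per ancestor + itself
#> $ associations        : int 753
#> $ significant_signals : int 1       <- exactly the planted drug-event pair
```

The planted target (50 evidence records at score 0.9 on one leaf disease)
ranks first for that disease:

```r
assoc <- data.table::fread(file.path(dir, "out", "associations.tsv"))
rank_query(assoc, ev$manifest$planted_associations[[1]]$disease,
           mode = "direct", top_k = 3)
#>          target_id  disease_id overall_score evidence_count
#> 1: ENSG00000000001 EFO_0100005     0.5510473             51
#> 2: ENSG00000000013 EFO_0100005     0.4325341              2
#> 3: ENSG00000000008 EFO_0100005     0.3970196              2
```

and the planted drug–event pair (relative risk 10) is the one significant
pharmacovigilance signal:

```r
data.table::fread(file.path(dir, "out", "signals.tsv"))[significant == TRUE]
#>        drug   event   nij    ni    nj     N     llr critical_value significant
#> 1: DRUG_001 EV_0020   172   365  1718 17540 139.622       4.572267        TRUE
```

Interpretation: DRUG_001 appears in 1,718 of 17,540 reliable reports and
co-occurs with EV_0020 172 times where ≈ 36 were expected; its
likelihood-ratio statistic 139.6 towers over the Monte-Carlo critical value
4.57 of the per-drug maximum statistic at α = 0.05.

Single-function entry points are exported too: `harmonic_sum()`,
`normalized_harmonic_sum()` (e.g. 50 scores of 0.9 → 0.8946; one score of
1.0 → 0.6117 under cap 100), `score_evidence()`, `ancestors()`,
`expand_evidence()`, `llr()`, `mc_critical_value()`, `detect_signals()`.

## Command line

An executable front end is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "tdassoc", package = "tdassoc"))')
Rscript $CLI simulate faers --seed 5 --out sim/
Rscript $CLI faers --reports sim/reports.tsv --alpha 0.05 --n-sims 1000 --seed 5 --out signals.tsv
Rscript $CLI run --config run.yaml
Rscript $CLI rank --associations out/associations.tsv --id EFO_0100005 --top-k 10
```

Exit codes: 0 success, 1 usage, 2 missing input, 3 schema/ontology error,
4 internal invariant violation.

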