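denom100 <- sum(1 / (1:100)^2)

test_that("harmonic_sum matches direct summation and rejects bad input", {
  expect_equal(harmonic_sum(numeric(0)), 0)
  for (s in c(0, 0.3, 1)) expect_equal(harmonic_sum(s), s)
  expect_equal(harmonic_sum(c(1, 1, 1), cap = 100), 1 + 1 / 4 + 1 / 9)
  expect_equal(harmonic_sum(c(1, 1, 1), cap = 2), 1 + 1 / 4)
  expect_error(harmonic_sum(c(0.5, 1.2)), "\\[0,1\\]",
               class = "tdassoc_input_error")
  expect_error(harmonic_sum(-0.1), class = "tdassoc_input_error")
})

test_that("normalized harmonic sum reaches exactly 1 at cap perfect scores", {
  cfg <- scoring_config()
  expect_equal(cfg$normalization_denominator, denom100, tolerance = 1e-12)
  expect_equal(normalized_harmonic_sum(0.5, cfg), 0.5 / denom100)
  expect_equal(normalized_harmonic_sum(rep(1, 100), cfg), 1)
  expect_equal(normalized_harmonic_sum(rep(1, 250), cfg), 1) # cap truncates
  expect_equal(normalized_harmonic_sum(numeric(0), cfg), 0)
  cfg5 <- scoring_config(cap = 5)
  expect_equal(cfg5$normalization_denominator, sum(1 / (1:5)^2),
               tolerance = 1e-12)
  expect_equal(normalized_harmonic_sum(rep(1, 5), cfg5), 1)
})

test_that("engine equals the direct-summation oracle on random vectors", {
  withr::local_seed(123)
  for (rep in 1:200) {
    v <- runif(sample.int(200, 1L))
    for (cap in c(2L, 10L, 100L)) {
      expect_equal(harmonic_sum(v, cap), oracle_harmonic(v, cap),
                   tolerance = 1e-12)
    }
  }
})

test_that("harmonic sums are monotone, bounded and permutation-invariant", {
  withr::local_seed(99)
  cfg <- scoring_config()
  for (rep in 1:100) {
    v <- runif(sample.int(50, 1L))
    x <- runif(1)
    expect_gte(harmonic_sum(c(v, x), cfg$cap), harmonic_sum(v, cfg$cap))
    s <- normalized_harmonic_sum(v, cfg)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_identical(normalized_harmonic_sum(sample(v), cfg), s)
  }
})

test_that("per-source scorers apply the published thresholds", {
  cfg <- scoring_config()

  gwas <- function(p, rs = 0.7) minimal_record(
    datasource_id = "ot_genetics_portal", resource_score = rs, gwas_pvalue = p)
  expect_true(is.na(score_evidence(gwas(1e-6), cfg)))      # above 5e-8: reject
  expect_equal(score_evidence(gwas(5e-8), cfg), 0.7)       # at the cutoff
  expect_equal(score_evidence(gwas(1e-12, rs = 1.4), cfg), 1) # clipped

  ps <- function(x) list(target_id = "ENSG00000000001",
                         disease_id = "EFO_0000001",
                         datasource_id = "project_score",
                         datatype_id = "affected_pathway",
                         score_payload = list(priority_score = x))
  expect_true(is.na(score_evidence(ps(39), cfg)))
  expect_equal(score_evidence(ps(40), cfg), 0.40)
  expect_equal(score_evidence(ps(87.5), cfg), 0.875)

  kd <- function(phase) minimal_record(datasource_id = "chembl",
                                       datatype_id = "known_drug",
                                       resource_score = NULL,
                                       clinical_phase = phase)
  expect_equal(score_evidence(kd(4L), cfg), 1.0)
  expect_equal(score_evidence(kd(0L), cfg), 0.05)

  expect_equal(score_evidence(minimal_record(resource_score = 0.33), cfg), 0.33)
  nores <- minimal_record(); nores$score_payload$resource_score <- NULL
  expect_error(score_evidence(nores, cfg), "resource_score",
               class = "tdassoc_input_error")

  # vectorised path tallies rejects
  tab <- evidence_table(c(lapply(c(1e-6, 1e-9), gwas),
                          lapply(c(10, 60), function(x) ps(x))))
  scored <- score_evidence_table(tab, cfg)
  expect_equal(unname(attr(scored, "reject_counts")), c(1L, 1L))
  expect_equal(scored$score, c(NA, 0.7, NA, 0.60))
})

test_that("weighted data-type and overall reductions follow weight-then-sort", {
  cfg <- scoring_config()
  expect_equal(datasource_association(0.8, cfg), 0.8 / denom100)
  expect_equal(datasource_association(c(0.8, 0.8), cfg), (0.8 + 0.2) / denom100)

  # single source, weight 1
  expect_equal(datatype_association(c(eva = 0.5), cfg), 0.5 / denom100)
  # weight 1 and weight 0.2 both at 1.0: down-weighted source lands second
  expect_equal(overall_association(c(eva = 1.0, europepmc = 1.0), cfg),
               (1.0 + 0.2 / 4) / denom100)
  expect_equal(overall_association(c(eva = 0, europepmc = 0), cfg), 0)
  expect_equal(overall_association(c(chembl = 1.0), cfg), 1 / denom100)
  # permutation invariance and zero-score neutrality
  expect_equal(overall_association(c(europepmc = 1.0, eva = 1.0), cfg),
               overall_association(c(eva = 1.0, europepmc = 1.0), cfg))
  expect_equal(overall_association(c(eva = 0.9, chembl = 0), cfg),
               overall_association(c(eva = 0.9), cfg))
  # explicit per-source weight overrides the data-type default
  cfg2 <- scoring_config(source_weights = c(eva = 0.5))
  expect_equal(overall_association(c(eva = 1.0), cfg2), 0.5 / denom100)
  expect_error(datatype_association(c(mystery_source = 0.5), cfg2),
               "unknown datasource", class = "tdassoc_input_error")
})

test_that("build_associations aggregates per pair in both modes", {
  cfg <- scoring_config()
  g <- chain_graph()

  # one evidence at leaf C propagates to 3 identically scored records
  ev <- score_evidence_table(evidence_table(list(
    minimal_record(disease_id = "EFO_0000003", resource_score = 0.6))), cfg)
  assoc <- build_associations(expand_evidence(g, ev), cfg)
  ind <- assoc[direct == FALSE]
  expect_equal(nrow(ind), 3L)
  # layered reduction: evidence -> source score, source scores -> overall
  expect_equal(unique(ind$ds_eva), 0.6 / denom100)
  expect_equal(unique(ind$overall_score), (0.6 / denom100) / denom100)
  expect_equal(assoc[direct == TRUE, disease_id], "EFO_0000003")

  # empty input
  expect_equal(nrow(build_associations(
    expand_evidence(g, evidence_table(list())), cfg)), 0L)

  # 50 pieces at 0.9 outrank 1 piece at 1.0 under cap 100
  mk <- function(tg, n, s) lapply(seq_len(n), function(i) {
    minimal_record(target_id = tg, disease_id = "EFO_0000003",
                   resource_score = s, study_id = sprintf("S%03d", i))
  })
  ev2 <- score_evidence_table(evidence_table(
    c(mk("ENSG00000000001", 50L, 0.9), mk("ENSG00000000002", 1L, 1.0))), cfg)
  assoc2 <- build_associations(expand_evidence(g, ev2), cfg)
  top <- assoc2[direct == TRUE]
  expect_equal(top$target_id[1], "ENSG00000000001")
  ds1 <- oracle_harmonic(rep(0.9, 50), 100) / denom100
  expect_equal(top$ds_eva[1], ds1)
  expect_equal(top$overall_score[1], ds1 / denom100)
  expect_gt(top$overall_score[1], top$overall_score[2])
  expect_equal(top$ds_eva[2], 1 / denom100)

  # dt_ columns: single-source data type reduces the same way as overall
  expect_equal(top$dt_genetic_association, top$ds_eva / denom100)
})

test_that("association tables are deterministic and ancestor-dominant", {
  cfg <- scoring_config()
  withr::local_seed(5)
  dag <- random_dag_edges(n_nodes = 15L, n_ta = 2L)
  g <- load_ontology(dag$edges, therapeutic_area_ids = dag$tas)
  recs <- lapply(1:60, function(i) {
    r <- random_conforming_record()
    r$disease_id <- sample(dag$ids, 1L)
    r$target_id <- sprintf("ENSG%011d", sample.int(5L, 1L))
    r
  })
  ev <- score_evidence_table(evidence_table(recs), cfg)
  expanded <- expand_evidence(g, ev)
  a1 <- build_associations(expanded, cfg)
  a2 <- build_associations(expanded, cfg)
  expect_identical(a1, a2)

  ind <- a1[direct == FALSE]
  for (i in seq_len(nrow(ind))) {
    anc <- ancestors(g, ind$disease_id[i])
    for (a in anc) {
      up <- ind[target_id == ind$target_id[i] & disease_id == a, overall_score]
      expect_gte(up, ind$overall_score[i])
    }
  }
})
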