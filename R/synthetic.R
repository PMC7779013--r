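#' Synthetic fixtures: ontologies, evidence sets and report tables
#'
#' Everything the pipeline consumes can be generated with planted structure
#' and a single seed, so the whole package builds and tests without any
#' external download. Generators are pure functions of their arguments
#' (seed included): reruns are byte-identical. Each generator also returns a
#' coverage manifest recording what was planted, so pipeline manifests can
#' be checked against generator intent.
#'
#' @name synthetic_data
NULL

#' Fixture specification with the package's stated-world defaults
#'
#' Defaults describe the world the acceptance properties are measured in:
#' a 30-term ontology with 3 therapeutic areas; 1,000 background evidence
#' records over 20 targets with Beta(2,5) scores (most evidence weak, a few
#' strong) plus one planted association of 50 records at score 0.9; a
#' 50,000-report adverse-event table over 20 drugs and 200 events (uniform
#' drug marginal, 1/rank event marginal) with one planted drug-event pair at
#' relative risk 10 and a small fixed fraction of rows violating each report
#' filter rule.
#'
#' @param seed master seed recorded in every output artifact.
#' @param ontology list: `n_nodes`, `max_parents`, `n_therapeutic_areas`.
#' @param evidence list: `n_targets`, `n_evidence`, `datasource_mix` (named
#'   sampling probabilities), `beta_shape1`, `beta_shape2`, `invalid_frac`,
#'   `gwas_fail_frac`, `low_priority_frac`.
#' @param planted_associations list of lists with `target`, `disease`
#'   (NULL = pick a leaf), `n_evidence`, `score_level`.
#' @param faers list: `n_reports`, `n_drugs`, `n_events`, `qual_bad_frac`,
#'   `role_bad_frac`, `dup_frac`, `blacklist_frac`.
#' @param planted_signals list of lists with `drug`, `event`,
#'   `relative_risk` (>= 1).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         ontology = list(),
                         evidence = list(),
                         planted_associations = NULL,
                         faers = list(),
                         planted_signals = NULL) {
  spec <- list(
    seed = as.integer(seed),
    ontology = modifyList(list(n_nodes = 30L, max_parents = 3L,
                               n_therapeutic_areas = 3L), ontology),
    evidence = modifyList(list(n_targets = 20L, n_evidence = 1000L,
                               datasource_mix = c(ot_genetics_portal = 0.3,
                                                  eva = 0.15, chembl = 0.15,
                                                  project_score = 0.1,
                                                  expression_atlas = 0.1,
                                                  europepmc = 0.15,
                                                  phenodigm = 0.05),
                               beta_shape1 = 2, beta_shape2 = 5,
                               invalid_frac = 0.02, gwas_fail_frac = 0.05,
                               low_priority_frac = 0.3), evidence),
    planted_associations = planted_associations %||%
      list(list(target = "ENSG00000000001", disease = NULL,
                n_evidence = 50L, score_level = 0.9)),
    faers = modifyList(list(n_reports = 50000L, n_drugs = 20L,
                            n_events = 200L, qual_bad_frac = 0.05,
                            role_bad_frac = 0.05, dup_frac = 0.02,
                            blacklist_frac = 0.02), faers),
    planted_signals = planted_signals %||%
      list(list(drug = "DRUG_001", event = "EV_0020", relative_risk = 10))
  )
  stopifnot(spec$ontology$n_nodes >= spec$ontology$n_therapeutic_areas + 2L,
            all(vapply(spec$planted_signals,
                       function(s) s$relative_risk >= 1, logical(1))))
  structure(spec, class = "fixture_spec")
}

synthetic_root_id <- "EFO_0000001"

#' Generate a random toy disease ontology
#'
#' A DAG built by topological rank: one generic root, the therapeutic areas
#' under it, then disease terms each choosing 1..`max_parents` parents among
#' earlier terms — acyclic by construction. Both an OBO file and a
#' child-parent edge TSV describing the same graph are written when
#' `out_dir` is given.
#'
#' @param spec a [fixture_spec()] (its `ontology` and `seed` fields are used).
#' @param out_dir optional directory for `ontology.obo` and
#'   `ontology_edges.tsv`.
#' @return list with `edges` (data.table child/parent), `nodes`,
#'   `therapeutic_areas`, `root_id`, `graph` (loaded `ontology_graph`) and,
#'   when written, `obo_path` / `tsv_path`.
#' @export
make_toy_ontology <- function(spec = fixture_spec(), out_dir = NULL) {
  o <- spec$ontology
  n_ta <- o$n_therapeutic_areas
  n_disease <- o$n_nodes - n_ta - 1L
  tas <- sprintf("EFO_%07d", 1000L + seq_len(n_ta))
  diseases <- sprintf("EFO_%07d", 100000L + seq_len(n_disease))
  nodes <- c(synthetic_root_id, tas, diseases)
  edges <- withr::with_seed(derive_seed(spec$seed, "ontology"), {
    e <- list(data.table(child = tas, parent = synthetic_root_id))
    earlier <- tas
    for (d in diseases) {
      k <- sample.int(min(o$max_parents, length(earlier)), 1L)
      e[[length(e) + 1L]] <- data.table(child = d,
                                        parent = sample(earlier, k))
      earlier <- c(earlier, d)
    }
    rbindlist(e)
  })
  graph <- load_ontology(edges, therapeutic_area_ids = tas,
                         root_ids = synthetic_root_id)
  out <- list(edges = edges, nodes = nodes, therapeutic_areas = tas,
              root_id = synthetic_root_id, graph = graph, seed = spec$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    obo <- file.path(out_dir, "ontology.obo")
    tsv <- file.path(out_dir, "ontology_edges.tsv")
    hdr <- c("format-version: 1.2",
             sprintf("remark: synthetic fixture ontology (seed %d)", spec$seed),
             "")
    stanzas <- unlist(lapply(nodes, function(n) {
      c("[Term]", sprintf("id: %s", n), sprintf("name: synthetic term %s", n),
        sprintf("is_a: %s ! parent", edges[child == n, parent]), "")
    }))
    writeLines(c(hdr, stanzas), obo)
    fwrite(edges, tsv, sep = "\t", col.names = FALSE)
    out$obo_path <- obo
    out$tsv_path <- tsv
  }
  out
}

synthetic_targets <- function(n) sprintf("ENSG%011d", seq_len(n))

#' Generate a synthetic evidence set with planted associations
#'
#' Background records draw a target, a disease term (any non-root term) and
#' a data source from the configured mix; scores follow Beta(2,5) by
#' default. Planted (target, disease) pairs receive the stated number of
#' records at the stated score level through the `eva` pass-through source.
#' A small configured fraction of records is deliberately schema-invalid
#' (bad target pattern / missing disease / bad data type), and
#' genetics-portal and CRISPR-screen records straddle their thresholds, so
#' every validator and scorer path is exercised. Per-record `study_id`
#' payload entries keep genuinely distinct evidence distinct under
#' payload-hash deduplication.
#'
#' @param spec a [fixture_spec()].
#' @param ontology output of [make_toy_ontology()] (asserted diseases are
#'   drawn from it).
#' @param path optional JSON Lines output path; a `<path>.manifest.json`
#'   coverage manifest is written next to it.
#' @return list with `records` (raw list, invalid ones included) and
#'   `manifest` (planted/invalid/reject expectations).
#' @export
make_evidence_set <- function(spec = fixture_spec(),
                              ontology = make_toy_ontology(spec),
                              path = NULL) {
  e <- spec$evidence
  targets <- synthetic_targets(e$n_targets)
  terms <- setdiff(ontology$nodes, ontology$root_id)
  leaf_terms <- setdiff(terms, c(ontology$therapeutic_areas,
                                 unique(ontology$edges$parent)))
  if (length(leaf_terms) == 0L) leaf_terms <- terms
  mix <- e$datasource_mix / sum(e$datasource_mix)

  res <- withr::with_seed(derive_seed(spec$seed, "evidence"), {
    n <- e$n_evidence
    tg <- sample(targets, n, replace = TRUE)
    ds <- sample(names(mix), n, replace = TRUE, prob = mix)
    dz <- sample(terms, n, replace = TRUE)
    sc <- rbeta(n, e$beta_shape1, e$beta_shape2)
    gwas_fail <- runif(n) < e$gwas_fail_frac
    low_prio <- runif(n) < e$low_priority_frac
    invalid <- runif(n) < e$invalid_frac
    invalid_kind <- sample(c("bad_target", "missing_disease", "bad_datatype"),
                           n, replace = TRUE)
    records <- vector("list", n)
    for (i in seq_len(n)) {
      src <- ds[i]
      payload <- switch(src,
        ot_genetics_portal = list(
          resource_score = round(sc[i], 6),
          gwas_pvalue = if (gwas_fail[i]) 1e-6 else 10^(-runif(1, 9, 30)),
          study_id = sprintf("GCST%06d", i)),
        project_score = list(
          priority_score = round(if (low_prio[i]) runif(1, 0, 39.5)
                                 else runif(1, 40, 100), 3)),
        chembl = list(clinical_phase = sample(0:4, 1L)),
        list(resource_score = round(sc[i], 6),
             study_id = sprintf("STUDY%06d", i)))
      rec <- list(target_id = tg[i], disease_id = dz[i], datasource_id = src,
                  datatype_id = unname(DEFAULT_DATASOURCE_TO_DATATYPE[src]),
                  score_payload = payload,
                  provenance = list(generator = "tdassoc-synthetic",
                                    seed = spec$seed))
      if (invalid[i]) {
        rec <- switch(invalid_kind[i],
          bad_target = { rec$target_id <- sprintf("GENE%04d", i); rec },
          missing_disease = { rec$disease_id <- NULL; rec },
          bad_datatype = { rec$datatype_id <- "genomics"; rec })
      }
      records[[i]] <- rec
    }
    planted <- list()
    for (p in spec$planted_associations) {
      dz_p <- p$disease %||% leaf_terms[1L]
      for (k in seq_len(p$n_evidence)) {
        planted[[length(planted) + 1L]] <- list(
          target_id = p$target, disease_id = dz_p, datasource_id = "eva",
          datatype_id = "genetic_association",
          score_payload = list(resource_score = p$score_level,
                               study_id = sprintf("PLANT%05d", k)),
          provenance = list(generator = "tdassoc-synthetic",
                            seed = spec$seed, planted = TRUE))
      }
    }
    list(records = c(records, planted),
         n_invalid = sum(invalid),
         n_gwas_reject = sum(gwas_fail & !invalid &
                               ds == "ot_genetics_portal"),
         n_priority_reject = sum(low_prio & !invalid & ds == "project_score"),
         planted_diseases = vapply(spec$planted_associations,
                                   function(p) p$disease %||% leaf_terms[1L],
                                   character(1)))
  })
  manifest <- list(
    seed = spec$seed,
    n_records = length(res$records),
    n_background = e$n_evidence,
    n_planted = length(res$records) - e$n_evidence,
    n_invalid = res$n_invalid,
    n_valid = length(res$records) - res$n_invalid,
    n_gwas_reject = res$n_gwas_reject,
    n_priority_reject = res$n_priority_reject,
    planted_associations = lapply(seq_along(spec$planted_associations),
      function(i) {
        p <- spec$planted_associations[[i]]
        list(target = p$target, disease = res$planted_diseases[i],
             n_evidence = p$n_evidence, score_level = p$score_level)
      })
  )
  if (!is.null(path)) {
    write_jsonl(res$records, path)
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(records = res$records, manifest = manifest)
}

#' Generate a synthetic adverse-event report table with planted signals
#'
#' Each report draws one drug from a uniform drug marginal and one event
#' from a 1/rank background event marginal; for planted (drug, event) pairs
#' the event's probability is multiplied by the relative risk and the drug's
#' event distribution renormalised, so report totals stay comparable across
#' drugs. Fixed fractions of rows violate each report-filter rule
#' (non-professional reporter, concomitant drug role, blacklisted event) and
#' a fraction of cases get a superseding version-2 row, so every filter path
#' is exercised.
#'
#' @param spec a [fixture_spec()].
#' @param path optional TSV output path; a `<path>.manifest.json` coverage
#'   manifest is written next to it.
#' @return list with `reports` (data.table) and `manifest`.
#' @export
make_faers_reports <- function(spec = fixture_spec(), path = NULL) {
  f <- spec$faers
  drugs <- sprintf("DRUG_%03d", seq_len(f$n_drugs))
  events <- sprintf("EV_%04d", seq_len(f$n_events))
  p_event <- (1 / seq_len(f$n_events)) / sum(1 / seq_len(f$n_events))
  # per-drug event distribution with planted relative risks, renormalised
  p_by_drug <- lapply(setNames(nm = drugs), function(d) p_event)
  for (s in spec$planted_signals) {
    stopifnot(s$drug %in% drugs, s$event %in% events)
    p <- p_by_drug[[s$drug]]
    p[match(s$event, events)] <- p[match(s$event, events)] * s$relative_risk
    p_by_drug[[s$drug]] <- p / sum(p)
  }
  res <- withr::with_seed(derive_seed(spec$seed, "faers"), {
    n <- f$n_reports
    drug <- sample(drugs, n, replace = TRUE)
    event <- character(n)
    for (d in drugs) {
      i <- drug == d
      event[i] <- sample(events, sum(i), replace = TRUE, prob = p_by_drug[[d]])
    }
    viol <- sample(c("none", "qual", "role", "blacklist"), n, replace = TRUE,
                   prob = c(1 - f$qual_bad_frac - f$role_bad_frac -
                              f$blacklist_frac,
                            f$qual_bad_frac, f$role_bad_frac,
                            f$blacklist_frac))
    qual <- ifelse(viol == "qual", "5",
                   sample(c("1", "2", "3"), n, replace = TRUE))
    role <- ifelse(viol == "role", "C",
                   sample(c("PS", "SS"), n, replace = TRUE, prob = c(.8, .2)))
    event[viol == "blacklist"] <- "drug ineffective"
    dt <- data.table(case_id = sprintf("CASE%08d", seq_len(n)),
                     drug = drug, event = event, qualification = qual,
                     drug_role = role, version = 1L)
    # superseding versions for a fraction of clean cases
    clean <- which(viol == "none")
    n_dup <- round(f$dup_frac * n)
    dup_idx <- if (n_dup > 0L) {
      sample(clean, min(n_dup, length(clean)))
    } else integer(0)
    dup <- dt[dup_idx]
    if (nrow(dup) > 0L) dup[, version := 2L]
    list(reports = rbindlist(list(dt, dup)),
         n_qual_bad = sum(viol == "qual"), n_role_bad = sum(viol == "role"),
         n_blacklist = sum(viol == "blacklist"), n_dup = length(dup_idx))
  })
  expected_pairs <- lapply(spec$planted_signals, function(s) {
    pd <- p_by_drug[[s$drug]][match(s$event, events)]
    list(drug = s$drug, event = s$event, relative_risk = s$relative_risk,
         expected_nij = unname(f$n_reports / f$n_drugs * pd))
  })
  manifest <- list(
    seed = spec$seed,
    n_rows = nrow(res$reports),
    n_reports = f$n_reports,
    n_qual_bad = res$n_qual_bad,
    n_role_bad = res$n_role_bad,
    n_blacklist = res$n_blacklist,
    n_duplicated_cases = res$n_dup,
    planted_signals = expected_pairs
  )
  if (!is.null(path)) {
    fwrite(res$reports, path, sep = "\t")
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(reports = res$reports, manifest = manifest)
}
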