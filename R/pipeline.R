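#' Pipeline orchestration: validate, expand, score, associate, detect
#'
#' A single configuration drives the full run: evidence is validated against
#' the schema, deduplicated, scored, expanded across the ontology and
#' aggregated into direct and indirect association tables; when a report
#' table is configured, the pharmacovigilance branch runs too. Every run
#' writes its resolved configuration and a manifest with input digests,
#' seeds and per-stage record counts next to its outputs, so reruns can be
#' checked for byte-identity.
#'
#' @name pipeline_cli
NULL

default_run_config <- function() {
  list(seed = 1L, schema = NULL, evidence = NULL, ontology = NULL,
       therapeutic_areas = character(0), root_ids = character(0),
       scoring = list(), reports = NULL,
       faers = list(alpha = 0.05, n_sims = 1000L),
       out_dir = "tdassoc_out")
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(input_error(sprintf("config file not found: %s", config)))
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  modifyList(default_run_config(), config)
}

#' Run the full pipeline
#'
#' Stages run in order: validate -> deduplicate -> score -> expand ->
#' associations, then (optionally) report filtering -> counts -> signal
#' detection. Any stage failure aborts after writing a partial manifest.
#'
#' @param config path to a YAML/JSON run configuration, or an equivalent
#'   named list. Keys: `seed`, `evidence` (JSONL path), `schema` (optional
#'   schema path), `ontology` (OBO or edge-TSV path), `therapeutic_areas`,
#'   `root_ids`, `scoring` (arguments to [scoring_config()]), `reports`
#'   (optional TSV path), `faers` (`alpha`, `n_sims`), `out_dir`.
#' @param out_dir overrides the configured output directory.
#' @return the run manifest, invisibly; outputs (`associations.tsv`,
#'   `associations.jsonl`, `signals.tsv`, `validation_report.json`,
#'   `resolved_config.yaml`, `manifest.json`) land in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  for (key in c("evidence", "ontology")) {
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]])) {
      stop(input_error(sprintf("missing %s input: %s", key,
                               cfg[[key]] %||% "<unset>")))
    }
  }
  if (!is.null(cfg$reports) && !file.exists(cfg$reports)) {
    stop(input_error(sprintf("missing reports input: %s", cfg$reports)))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  schema <- evidence_schema(cfg$schema)
  graph <- load_ontology(cfg$ontology,
                         therapeutic_area_ids = cfg$therapeutic_areas,
                         root_ids = cfg$root_ids)
  sconf <- do.call(scoring_config, cfg$scoring)

  val <- validate_evidence(cfg$evidence, schema)
  deduped <- deduplicate_evidence(val$evidence)
  ev <- evidence_table(deduped)
  scored <- score_evidence_table(ev, sconf)
  n_rejected <- sum(is.na(scored$score))
  scored <- scored[!is.na(score)]
  expanded <- expand_evidence(graph, scored)
  n_unresolvable <- nrow(attr(expanded, "rejects"))
  assoc <- build_associations(expanded, sconf)

  if (nrow(assoc) > 0L &&
      (any(assoc$overall_score < 0 | assoc$overall_score > 1) ||
       any(assoc$evidence_count < 1))) {
    stop(structure(class = c("tdassoc_invariant_error", "error", "condition"),
                   list(message = "association invariant violated",
                        call = NULL)))
  }

  paths <- list(
    associations_tsv = file.path(cfg$out_dir, "associations.tsv"),
    associations_jsonl = file.path(cfg$out_dir, "associations.jsonl"),
    validation_report = file.path(cfg$out_dir, "validation_report.json"),
    resolved_config = file.path(cfg$out_dir, "resolved_config.yaml"),
    manifest = file.path(cfg$out_dir, "manifest.json")
  )
  fwrite(assoc, paths$associations_tsv, sep = "\t")
  write_jsonl(lapply(seq_len(nrow(assoc)), function(i) as.list(assoc[i])),
              paths$associations_jsonl)
  jsonlite::write_json(
    list(n_input = val$report$n_input, n_valid = val$report$n_valid,
         n_invalid = val$report$n_invalid,
         failures = val$report$failures),
    paths$validation_report, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  signals <- NULL
  if (!is.null(cfg$reports)) {
    reports <- fread(cfg$reports, sep = "\t",
                     colClasses = list(character = c("case_id", "drug",
                                                     "event", "qualification",
                                                     "drug_role")))
    filtered <- filter_reports(reports)
    counts <- aggregate_counts(filtered)
    signals <- detect_signals(counts, alpha = cfg$faers$alpha,
                              n_sims = cfg$faers$n_sims, seed = cfg$seed)
    paths$signals_tsv <- file.path(cfg$out_dir, "signals.tsv")
    fwrite(signals, paths$signals_tsv, sep = "\t")
  }

  yaml::write_yaml(cfg, paths$resolved_config)
  manifest <- list(
    config_hash = digest::digest(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed,
    inputs = list(evidence = file_digest(cfg$evidence),
                  ontology = file_digest(cfg$ontology),
                  reports = if (is.null(cfg$reports)) NULL
                            else file_digest(cfg$reports)),
    counts = list(
      input = val$report$n_input, valid = val$report$n_valid,
      invalid = val$report$n_invalid,
      deduplicated = length(deduped),
      score_rejected = n_rejected,
      scored = nrow(scored),
      unresolvable_disease = n_unresolvable,
      expanded = nrow(expanded),
      associations = nrow(assoc),
      signals = if (is.null(signals)) NULL else nrow(signals),
      significant_signals = if (is.null(signals)) NULL
                            else sum(signals$significant)
    ),
    artifacts = paths[names(paths) != "manifest"],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Ranked association query
#'
#' Top-k associations for one disease (ranked targets) or one target (ranked
#' diseases), in direct or indirect mode, sorted by overall score with the
#' documented tie-break (evidence count descending, then id ascending).
#'
#' @param associations association table from [build_associations()] or read
#'   back from `associations.tsv`.
#' @param id a disease term id or a target id (Ensembl-style ids are treated
#'   as targets).
#' @param mode `"indirect"` (direct + propagated evidence, the default) or
#'   `"direct"` (evidence asserted at the term itself only).
#' @param top_k number of rows to return (clamped to the table).
#' @return the ranked slice; empty (with a warning) for an unknown id.
#' @export
rank_query <- function(associations, id, mode = c("indirect", "direct"),
                       top_k = 25L) {
  mode <- match.arg(mode)
  a <- as.data.table(associations)
  a <- a[direct == (mode == "direct")]
  hit <- if (grepl("^ENSG", id)) a[target_id == id] else a[disease_id == id]
  if (nrow(hit) == 0L) {
    warning(sprintf("no associations for id %s in %s mode", id, mode))
    return(hit)
  }
  setorderv(hit, c("overall_score", "evidence_count", "target_id",
                   "disease_id"),
            order = c(-1L, -1L, 1L, 1L))
  head(hit, top_k)
}
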