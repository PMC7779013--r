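#' Association scoring: harmonic-sum aggregation of evidence
#'
#' Every piece of evidence is first scored in \[0,1\] by a per-source scorer.
#' Evidence for one (target, disease, data source) is aggregated by a
#' normalized harmonic sum: scores are sorted in descending order and summed
#' as \eqn{\sum_i s_{(i)}/i^2} over at most `cap` terms, then divided by
#' \eqn{\sum_{i=1}^{cap} 1/i^2} so the result lies in \[0,1\]. Data-source
#' scores are combined into data-type scores and an overall association score
#' by the same reduction applied to weight-multiplied source scores. Many
#' independent pieces of evidence therefore boost an association with
#' diminishing returns, and one strong source can never be crowded out by
#' down-weighted ones.
#'
#' @name association_scoring
NULL

DEFAULT_SOURCE_SCORERS <- c(
  ot_genetics_portal = "genetics_portal",
  project_score = "project_score",
  chembl = "known_drug"
)

DEFAULT_DATASOURCE_TO_DATATYPE <- c(
  ot_genetics_portal = "genetic_association",
  eva = "genetic_association",
  gene2phenotype = "genetic_association",
  cancer_gene_census = "somatic_mutation",
  intogen = "somatic_mutation",
  chembl = "known_drug",
  project_score = "affected_pathway",
  reactome = "affected_pathway",
  expression_atlas = "rna_expression",
  europepmc = "literature",
  phenodigm = "animal_model"
)

#' Build a scoring configuration
#'
#' @param cap maximum number of evidence terms contributing to a harmonic sum
#'   (default 100); the normalisation denominator is
#'   \eqn{\sum_{i=1}^{cap} 1/i^2}.
#' @param source_weights named numeric vector, datasource id -> weight in
#'   (0,1]. Sources absent from the map get weight 1 for their data type's
#'   default (see `datatype_weights`).
#' @param datatype_weights named numeric vector datatype id -> weight in
#'   (0,1], used for any source without an explicit weight. Defaults: 1 for
#'   genetic_association, somatic_mutation, known_drug, affected_pathway;
#'   0.2 for rna_expression, literature, animal_model.
#' @param datasource_to_datatype named character vector mapping datasource id
#'   to one of the seven data types.
#' @param source_scorers named character vector mapping datasource id to a
#'   scorer in `c("genetics_portal", "project_score", "known_drug",
#'   "passthrough")`; unmapped sources use the pass-through scorer
#'   (clipped `resource_score`).
#' @param phase_score_map numeric vector of length 5 mapping clinical trial
#'   phases 0..4 to scores in \[0,1\].
#' @param gwas_pvalue_cutoff GWAS significance threshold; genetics-portal
#'   evidence with a larger p-value is rejected (default 5e-8).
#' @param project_score_min minimum CRISPR-screen priority score (0-100
#'   scale) for project-score evidence to count (default 40).
#' @return a `scoring_config` object.
#' @export
scoring_config <- function(cap = 100L,
                           source_weights = NULL,
                           datatype_weights = c(genetic_association = 1,
                                                somatic_mutation = 1,
                                                known_drug = 1,
                                                affected_pathway = 1,
                                                rna_expression = 0.2,
                                                literature = 0.2,
                                                animal_model = 0.2),
                           datasource_to_datatype = DEFAULT_DATASOURCE_TO_DATATYPE,
                           source_scorers = DEFAULT_SOURCE_SCORERS,
                           phase_score_map = c(`0` = 0.05, `1` = 0.1, `2` = 0.2,
                                               `3` = 0.7, `4` = 1.0),
                           gwas_pvalue_cutoff = 5e-8,
                           project_score_min = 40) {
  cap <- as.integer(cap)
  stopifnot(cap >= 1L,
            all(datatype_weights > 0), all(datatype_weights <= 1),
            all(phase_score_map >= 0), all(phase_score_map <= 1),
            length(phase_score_map) == 5L,
            gwas_pvalue_cutoff > 0, gwas_pvalue_cutoff < 1)
  if (!is.null(source_weights)) {
    stopifnot(all(source_weights > 0), all(source_weights <= 1))
  }
  stopifnot(all(datasource_to_datatype %in% DATATYPE_IDS))
  structure(list(
    cap = cap,
    source_weights = source_weights,
    datatype_weights = datatype_weights,
    datasource_to_datatype = datasource_to_datatype,
    source_scorers = source_scorers,
    phase_score_map = phase_score_map,
    gwas_pvalue_cutoff = gwas_pvalue_cutoff,
    project_score_min = project_score_min,
    normalization_denominator = sum(1 / (seq_len(cap))^2)
  ), class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat(sprintf(paste0("scoring config: cap %d (denominator %.6f), ",
                     "GWAS p <= %g, priority score >= %g\n"),
              x$cap, x$normalization_denominator, x$gwas_pvalue_cutoff,
              x$project_score_min))
  invisible(x)
}

# effective weight of a datasource: explicit source weight, else its data
# type's default, else 1
source_weight <- function(config, datasource_id) {
  w <- config$source_weights[datasource_id]
  if (!is.null(config$source_weights) && !is.na(w)) return(unname(w))
  dt <- config$datasource_to_datatype[datasource_id]
  if (!is.na(dt)) {
    dw <- config$datatype_weights[dt]
    if (!is.na(dw)) return(unname(dw))
  }
  1
}

datasource_datatype <- function(config, datasource_id) {
  dt <- config$datasource_to_datatype[datasource_id]
  ifelse(is.na(dt), "literature", unname(dt))
}

#' Score one evidence record in \[0,1\]
#'
#' Dispatches on the data source's registered scorer:
#' * `genetics_portal`: reject (NA) when `gwas_pvalue` exceeds the cutoff,
#'   else the clipped `resource_score`;
#' * `project_score`: reject when `priority_score` is below the floor, else
#'   `priority_score / 100`;
#' * `known_drug`: the phase-score map applied to `clinical_phase`;
#' * `passthrough` (default): the clipped `resource_score`.
#'
#' `NA_real_` means REJECT: the record contributes nothing downstream.
#'
#' @param record one validated evidence record (list form), or one row of an
#'   [evidence_table()].
#' @param config a [scoring_config()].
#' @return numeric score in \[0,1\], or `NA_real_` for a rejected record.
#' @export
score_evidence <- function(record, config = scoring_config()) {
  if (is.data.frame(record)) {
    row <- as.data.table(record)
  } else {
    row <- evidence_table(list(record))
  }
  score_evidence_table(row, config)$score
}

#' Score a whole evidence table
#'
#' Vectorised form of [score_evidence()]: adds a `score` column (`NA` =
#' rejected) and returns the table; rejection reasons are tallied in the
#' `reject_counts` attribute.
#'
#' @param ev an [evidence_table()].
#' @param config a [scoring_config()].
#' @return the table with a `score` column appended.
#' @export
score_evidence_table <- function(ev, config = scoring_config()) {
  ev <- copy(as.data.table(ev))
  n <- nrow(ev)
  scorer <- config$source_scorers[ev$datasource_id]
  scorer[is.na(scorer)] <- "passthrough"
  s <- rep(NA_real_, n)
  rejects <- c(gwas_pvalue = 0L, priority_score = 0L)

  clip01 <- function(x) pmin(pmax(x, 0), 1)

  i <- scorer == "genetics_portal"
  if (any(i)) {
    pv <- ev$gwas_pvalue[i]
    pass <- is.na(pv) | pv <= config$gwas_pvalue_cutoff
    s[i] <- ifelse(pass, clip01(ev$resource_score[i]), NA_real_)
    rejects["gwas_pvalue"] <- sum(!pass)
  }
  i <- scorer == "project_score"
  if (any(i)) {
    ps <- ev$priority_score[i]
    pass <- !is.na(ps) & ps >= config$project_score_min
    s[i] <- ifelse(pass, ps / 100, NA_real_)
    rejects["priority_score"] <- sum(!pass)
  }
  i <- scorer == "known_drug"
  if (any(i)) {
    ph <- ev$clinical_phase[i]
    if (any(is.na(ph))) {
      stop(input_error("known-drug evidence without clinical_phase"))
    }
    s[i] <- unname(config$phase_score_map[as.character(ph)])
  }
  i <- scorer == "passthrough"
  if (any(i)) {
    rs <- ev$resource_score[i]
    if (any(is.na(rs))) {
      bad <- which(i)[which(is.na(rs))[1L]]
      stop(input_error(sprintf(
        "no registered scorer and no resource_score for record %d (source %s)",
        bad, ev$datasource_id[bad])))
    }
    s[i] <- clip01(rs)
  }
  ev[, score := s]
  setattr(ev, "reject_counts", rejects)
  ev[]
}

#' Raw harmonic sum of a score vector
#'
#' Scores are sorted in descending order; the sum
#' \eqn{\sum_{i=1}^{\min(n, cap)} s_{(i)}/i^2} is returned. Appending a score
#' can never decrease the result.
#'
#' @param scores numeric vector of values in \[0,1\].
#' @param cap maximum number of contributing terms.
#' @return non-negative numeric scalar.
#' @export
harmonic_sum <- function(scores, cap = 100L) {
  if (length(scores) == 0L) return(0)
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop(input_error("harmonic_sum: scores must lie in [0,1]"))
  }
  s <- sort(scores, decreasing = TRUE)
  n <- min(length(s), as.integer(cap))
  sum(s[seq_len(n)] / (seq_len(n))^2)
}

#' Normalized harmonic sum in \[0,1\]
#'
#' [harmonic_sum()] divided by \eqn{\sum_{i=1}^{cap} 1/i^2}, so `cap` copies
#' of a perfect score give exactly 1.
#'
#' @param scores numeric vector of values in \[0,1\].
#' @param config a [scoring_config()] supplying `cap` and the precomputed
#'   denominator.
#' @return score in \[0,1\].
#' @export
normalized_harmonic_sum <- function(scores, config = scoring_config()) {
  harmonic_sum(scores, config$cap) / config$normalization_denominator
}

#' Data-source association score
#'
#' Normalized harmonic sum of the (already scored, rejects removed) evidence
#' for one (target, disease, datasource).
#'
#' @param evidence_scores numeric vector of per-evidence scores in \[0,1\].
#' @param config a [scoring_config()].
#' @return score in \[0,1\].
#' @export
datasource_association <- function(evidence_scores, config = scoring_config()) {
  normalized_harmonic_sum(evidence_scores, config)
}

# weighted reduction shared by datatype_association / overall_association:
# multiply each source score by its weight, then sort and harmonic-sum
weighted_harmonic <- function(datasource_scores, config) {
  ids <- names(datasource_scores)
  if (is.null(ids) && length(datasource_scores) > 0L) {
    stop(input_error("datasource scores must be named by datasource id"))
  }
  w <- vapply(ids, function(d) source_weight(config, d), numeric(1))
  normalized_harmonic_sum(unname(datasource_scores) * unname(w), config)
}

#' Data-type association score
#'
#' Weighted harmonic sum over the data-source scores belonging to one data
#' type: each source score is multiplied by its weight before the descending
#' sort and harmonic reduction.
#'
#' @param datasource_scores named numeric vector (datasource id -> score in
#'   \[0,1\]) for sources of a single data type.
#' @param config a [scoring_config()].
#' @return score in \[0,1\].
#' @export
datatype_association <- function(datasource_scores, config = scoring_config()) {
  unknown <- setdiff(names(datasource_scores),
                     names(config$datasource_to_datatype))
  if (length(unknown) > 0L && !is.null(config$source_weights)) {
    # unknown sources are only an error when an explicit weight table is in
    # force and silent weight-1 defaults could surprise
    unknown <- setdiff(unknown, names(config$source_weights))
    if (length(unknown) > 0L) {
      stop(input_error(sprintf("unknown datasource(s): %s",
                               paste(unknown, collapse = ", "))))
    }
  }
  weighted_harmonic(datasource_scores, config)
}

#' Overall association score
#'
#' Weighted harmonic sum of all individual data-source scores for one
#' (target, disease); this is the score that ranks targets for a disease.
#'
#' @inheritParams datatype_association
#' @return score in \[0,1\].
#' @export
overall_association <- function(datasource_scores, config = scoring_config()) {
  weighted_harmonic(datasource_scores, config)
}

#' Build the association table from expanded, scored evidence
#'
#' Produces one association record per (target, disease) in two modes:
#' `direct = TRUE` rows aggregate only evidence asserted at the disease term
#' itself; `direct = FALSE` rows aggregate the union of direct and
#' ontology-propagated evidence. Each record carries per-source scores
#' (`ds_*` columns), per-type scores (`dt_*` columns), the overall score and
#' the evidence count. Rows are sorted by overall score descending, ties
#' broken by evidence count descending then target id (and disease id)
#' ascending.
#'
#' @param expanded output of [expand_evidence()] with a `score` column from
#'   [score_evidence_table()] (rejected rows, `score` NA, are dropped here).
#' @param config a [scoring_config()].
#' @return data.table of association records.
#' @export
build_associations <- function(expanded, config = scoring_config()) {
  ev <- as.data.table(expanded)
  empty <- data.table(target_id = character(0), disease_id = character(0),
                      direct = logical(0), overall_score = numeric(0),
                      evidence_count = integer(0))
  if (nrow(ev) == 0L) return(empty)
  if (!"score" %in% names(ev)) {
    stop(input_error("expanded evidence has no score column; run score_evidence_table first"))
  }
  ev <- ev[!is.na(score)]
  if (nrow(ev) == 0L) return(empty)

  one_mode <- function(sub, mode_direct) {
    if (nrow(sub) == 0L) return(empty)
    ds <- sub[, .(ds_score = datasource_association(score, config),
                  n_ev = .N),
              by = .(target_id, disease_id, datasource_id)]
    ds[, datatype_id := datasource_datatype(config, datasource_id)]
    per_pair <- ds[, .(overall_score = overall_association(
                         setNames(ds_score, datasource_id), config),
                       evidence_count = sum(n_ev)),
                   by = .(target_id, disease_id)]
    per_type <- ds[, .(dt_score = datatype_association(
                         setNames(ds_score, datasource_id), config)),
                   by = .(target_id, disease_id, datatype_id)]
    ds_wide <- dcast(ds, target_id + disease_id ~ paste0("ds_", datasource_id),
                     value.var = "ds_score", fill = 0)
    dt_wide <- dcast(per_type, target_id + disease_id ~ paste0("dt_", datatype_id),
                     value.var = "dt_score", fill = 0)
    per_pair <- merge(per_pair, ds_wide, by = c("target_id", "disease_id"))
    per_pair <- merge(per_pair, dt_wide, by = c("target_id", "disease_id"))
    per_pair[, direct := mode_direct]
    per_pair
  }

  out <- rbindlist(list(one_mode(ev[direct == TRUE], TRUE),
                        one_mode(ev, FALSE)),
                   use.names = TRUE, fill = TRUE)
  score_cols <- grep("^(ds|dt)_", names(out), value = TRUE)
  for (cc in score_cols) out[is.na(get(cc)), (cc) := 0]
  setorderv(out, c("overall_score", "evidence_count", "target_id", "disease_id"),
            order = c(-1L, -1L, 1L, 1L))
  setcolorder(out, c("target_id", "disease_id", "direct", "overall_score",
                     "evidence_count"))
  out[]
}
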