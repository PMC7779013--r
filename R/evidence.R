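#' Evidence data model: schema validation and deduplication
#'
#' An evidence string is one unit of support linking a target (Ensembl-gene
#' style identifier) to a disease (ontology CURIE) through a data source of a
#' given data type, with a source-specific numeric/categorical score payload.
#' Records arrive as JSON objects (typically JSON Lines) and are validated
#' against a schema document shipped with the package before anything
#' downstream touches them.
#'
#' @name evidence_model
NULL

DATATYPE_IDS <- c("genetic_association", "somatic_mutation", "known_drug",
                  "affected_pathway", "rna_expression", "literature",
                  "animal_model")

#' Load the shipped evidence schema
#'
#' @param path optional path to an alternative schema document; defaults to
#'   the JSON-schema-style contract installed with the package.
#' @return parsed schema (named list).
#' @export
evidence_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "evidence-schema.json", package = "tdassoc")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(schema_error(sprintf("schema document not found: %s", path)))
  }
  schema <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) stop(schema_error(paste("unparseable schema:",
                                                conditionMessage(e)))))
  if (!is.list(schema) || is.null(schema$properties)) {
    stop(schema_error("schema has no 'properties' member"))
  }
  schema
}

# Check a single scalar field against its property spec; returns character()
# when valid, otherwise rule-violation strings. Supports the subset of
# JSON-schema keywords the shipped contract uses: type, pattern, enum,
# minimum, maximum.
check_property <- function(value, prop, field) {
  fails <- character(0)
  bad_scalar <- function() length(value) != 1L || is.null(value) ||
    (length(value) == 1L && is.na(value))
  type <- prop$type %||% NULL
  if (!is.null(type) && type %in% c("string", "number", "integer")) {
    if (bad_scalar()) return(sprintf("type violation: %s", field))
    if (type == "string" && !is.character(value)) {
      return(sprintf("type violation: %s", field))
    }
    if (type %in% c("number", "integer")) {
      if (!is.numeric(value)) return(sprintf("type violation: %s", field))
      if (type == "integer" && value != trunc(value)) {
        return(sprintf("type violation: %s", field))
      }
    }
  }
  if (!is.null(prop$pattern) && !grepl(prop$pattern, value)) {
    fails <- c(fails, sprintf("pattern mismatch: %s", field))
  }
  if (!is.null(prop$enum) && !value %in% unlist(prop$enum)) {
    fails <- c(fails, sprintf("enum violation: %s", field))
  }
  if (!is.null(prop$minimum) && value < prop$minimum) {
    fails <- c(fails, sprintf("range violation: %s", field))
  }
  if (!is.null(prop$maximum) && value > prop$maximum) {
    fails <- c(fails, sprintf("range violation: %s", field))
  }
  fails
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All rule violations for one record; character(0) means valid.
validate_record <- function(record, schema) {
  if (inherits(record, "jsonl_parse_error")) return("malformed JSON")
  if (!is.list(record)) return("type violation: record is not an object")
  fails <- character(0)
  for (req in unlist(schema$required)) {
    v <- record[[req]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      fails <- c(fails, sprintf("required field absent: %s", req))
    }
  }
  for (field in names(schema$properties)) {
    v <- record[[field]]
    if (is.null(v)) next
    prop <- schema$properties[[field]]
    if (identical(prop$type, "object")) {
      if (!is.list(v)) {
        fails <- c(fails, sprintf("type violation: %s", field))
        next
      }
      for (sub in names(prop$properties)) {
        sv <- v[[sub]]
        if (is.null(sv)) next
        fails <- c(fails, check_property(sv, prop$properties[[sub]],
                                         paste(field, sub, sep = ".")))
      }
    } else {
      fails <- c(fails, check_property(v, prop, field))
    }
  }
  fails
}

#' Validate a stream of raw evidence records against the schema
#'
#' Invalid records are excluded (never repaired) and itemised in the report;
#' input order is preserved among valid records. A malformed JSON line counts
#' as one invalid record.
#'
#' @param records a list of parsed JSON objects, or a path to a JSON Lines
#'   file (one evidence object per line, UTF-8).
#' @param schema schema document from [evidence_schema()].
#' @return a list with components `evidence` (the valid records, in input
#'   order) and `report`, a validation report with fields `n_input`,
#'   `n_valid`, `n_invalid` and `failures` (a data.table of record index and
#'   rule violated).
#' @export
validate_evidence <- function(records, schema = evidence_schema()) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_jsonl(records)
  }
  stopifnot(is.list(records))
  fails <- vector("list", length(records))
  ok <- logical(length(records))
  for (i in seq_along(records)) {
    f <- validate_record(records[[i]], schema)
    ok[i] <- length(f) == 0L
    if (!ok[i]) fails[[i]] <- data.table(index = i, rule = f)
  }
  failures <- rbindlist(fails)
  if (nrow(failures) == 0L) {
    failures <- data.table(index = integer(0), rule = character(0))
  }
  report <- structure(
    list(n_input = length(records), n_valid = sum(ok),
         n_invalid = sum(!ok), failures = failures),
    class = "validation_report")
  list(evidence = records[ok], report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("evidence validation: %d input, %d valid, %d invalid\n",
              x$n_input, x$n_valid, x$n_invalid))
  if (x$n_invalid > 0L) {
    tab <- x$failures[, .N, by = "rule"]
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %s: %d\n", tab$rule[i], tab$N[i]))
    }
  }
  invisible(x)
}

# Duplicate key: identity fields plus a canonical (key-sorted) hash of the
# score payload, so byte-identical resubmissions collapse while genuinely
# different evidence for the same triple survives.
evidence_key <- function(record) {
  paste(record$target_id, record$disease_id, record$datasource_id,
        digest::digest(canonical_json(record$score_payload %||% list())),
        sep = "|")
}

#' Deduplicate validated evidence
#'
#' At most one record survives per (target, disease, datasource, canonical
#' payload hash); the first occurrence wins, and input order is preserved.
#'
#' @param records list of validated evidence records.
#' @return deduplicated list, order-stable.
#' @export
deduplicate_evidence <- function(records) {
  keys <- vapply(records, evidence_key, character(1))
  records[!duplicated(keys)]
}

#' Convert evidence records to a flat table
#'
#' Flattens validated evidence into the data.table consumed by scoring and
#' ontology expansion; payload fields absent from a record become NA.
#'
#' @param records list of validated evidence records.
#' @return data.table with one row per record and an `evidence_id` row index.
#' @export
evidence_table <- function(records) {
  if (length(records) == 0L) {
    return(data.table(evidence_id = integer(0), target_id = character(0),
                      disease_id = character(0), datasource_id = character(0),
                      datatype_id = character(0), resource_score = numeric(0),
                      gwas_pvalue = numeric(0), priority_score = numeric(0),
                      clinical_phase = integer(0)))
  }
  num_or_na <- function(r, f) {
    v <- r$score_payload[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  data.table(
    evidence_id = seq_along(records),
    target_id = vapply(records, function(r) r$target_id, character(1)),
    disease_id = vapply(records, function(r) r$disease_id, character(1)),
    datasource_id = vapply(records, function(r) r$datasource_id, character(1)),
    datatype_id = vapply(records, function(r) r$datatype_id, character(1)),
    resource_score = vapply(records, num_or_na, numeric(1), "resource_score"),
    gwas_pvalue = vapply(records, num_or_na, numeric(1), "gwas_pvalue"),
    priority_score = vapply(records, num_or_na, numeric(1), "priority_score"),
    clinical_phase = as.integer(vapply(records, num_or_na, numeric(1),
                                       "clinical_phase"))
  )
}
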