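#' @importFrom data.table data.table as.data.table setorder setorderv := .N .SD .I
#'   rbindlist dcast uniqueN fwrite fread copy setnames setcolorder
#' @importFrom stats rbeta rbinom rmultinom runif quantile setNames
#' @importFrom utils head modifyList
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "..keep", "case_id", "critical_value", "datasource_id", "datatype_id",
  "direct", "disease_id", "drug", "drug_role", "ds_score", "dt_score",
  "event", "evidence_count", "evidence_id", "llr", "n_ev", "n_pair", "nij",
  "ni", "nj", "overall_score", "qualification", "score", "significant",
  "target_id", "version", "w", "weight", "child", "parent"
))

#' Read JSON Lines
#'
#' Reads a UTF-8 JSON Lines file into a list of parsed objects. Lines that do
#' not parse are kept as objects of class `jsonl_parse_error` so downstream
#' validation can count them as invalid rather than aborting.
#'
#' @param path file path.
#' @return list of parsed records (malformed lines flagged, not dropped).
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) {
    stop(input_error(sprintf("input file not found: %s", path)))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    tryCatch(
      jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                         simplifyMatrix = FALSE),
      error = function(e) structure(list(line = ln), class = "jsonl_parse_error")
    )
  })
}

#' Write JSON Lines
#'
#' @param records list of records (each serialised as one JSON object).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

# classed conditions so the CLI can map failures to exit codes
input_error <- function(msg) {
  structure(class = c("tdassoc_input_error", "error", "condition"),
            list(message = msg, call = NULL))
}
schema_error <- function(msg) {
  structure(class = c("tdassoc_schema_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Derive a deterministic child seed from a master seed and a string id
#'
#' A 32-bit polynomial hash of the id combined with the master seed, kept
#' below 2^31 so it is always a valid R integer seed. Used so per-drug
#' Monte-Carlo runs do not depend on drug processing order.
#'
#' @param master integer master seed.
#' @param id character scalar.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, id) {
  stopifnot(length(id) == 1L, is.character(id))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (c in utf8ToInt(id)) h <- (h * 31 + c) %% m
  as.integer((abs(as.numeric(master)) + h) %% m)
}

# canonical (key-sorted, recursively) serialisation of a payload, for hashing
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
      lapply(v, sort_rec)
    } else v
  }
  as.character(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

file_digest <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  digest::digest(path, algo = "sha256", file = TRUE)
}
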