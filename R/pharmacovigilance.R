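#' Pharmacovigilance: LRT signal detection in spontaneous-report tables
#'
#' Post-marketing adverse-event reports (FAERS-style) are filtered to the
#' most reliable entries, aggregated into drug x event contingency counts
#' over distinct reports, and screened for disproportionality with a
#' one-sided binomial likelihood-ratio statistic. For a drug with `nj`
#' reports, an event with overall frequency `ni/N` and co-mention count
#' `nij`, the expected count is `Eij = ni * nj / N` and
#' \deqn{LLR = n_{ij}\log\frac{n_{ij}}{E_{ij}} +
#'       (n_j - n_{ij})\log\frac{n_j - n_{ij}}{n_j - E_{ij}}}
#' when `nij > Eij`, else 0. Significance is assessed against the
#' (1 - alpha) quantile of the per-drug maximum LLR under a Monte-Carlo null
#' that reallocates the drug's reports across events multinomially with the
#' background event frequencies, which controls the per-drug family-wise
#' false-positive rate at about alpha and implicitly corrects for how often
#' the drug and the event each appear in reports.
#'
#' @name pharmacovigilance
NULL

DEFAULT_EVENT_BLACKLIST_FILE <- function() {
  system.file("extdata", "event-blacklist.txt", package = "tdassoc")
}

#' Filter configuration for adverse-event report tables
#'
#' @param qualification_whitelist reporter-qualification codes to keep
#'   (default: health-professional codes "1" physician, "2" pharmacist,
#'   "3" other health professional).
#' @param drug_role_whitelist drug-role codes to keep (default "PS", primary
#'   suspect, and "SS", secondary suspect).
#' @param event_blacklist uninformative event terms to drop; defaults to the
#'   editable list shipped in `inst/extdata/event-blacklist.txt`.
#' @return a plain list used by [filter_reports()].
#' @export
report_filter_config <- function(qualification_whitelist = c("1", "2", "3"),
                                 drug_role_whitelist = c("PS", "SS"),
                                 event_blacklist = NULL) {
  if (is.null(event_blacklist)) {
    f <- DEFAULT_EVENT_BLACKLIST_FILE()
    event_blacklist <- if (nzchar(f) && file.exists(f)) {
      readLines(f, warn = FALSE)
    } else character(0)
    event_blacklist <- event_blacklist[nzchar(trimws(event_blacklist))]
    event_blacklist <- event_blacklist[!grepl("^#", event_blacklist)]
  }
  list(qualification_whitelist = as.character(qualification_whitelist),
       drug_role_whitelist = as.character(drug_role_whitelist),
       event_blacklist = tolower(event_blacklist))
}

#' Filter a report table down to reliable entries
#'
#' Applies, in order: (1) keep reporter qualifications on the whitelist;
#' (2) keep drug roles on the whitelist; (3) deduplicate by case id, keeping
#' only rows of the highest report version; (4) drop blacklisted
#' uninformative event terms. Per-rule removal counts are attached as the
#' `removal_counts` attribute.
#'
#' @param rows data.frame/data.table with columns `case_id`, `drug`, `event`,
#'   `qualification`, `drug_role`, `version`.
#' @param config a [report_filter_config()].
#' @return filtered data.table.
#' @export
filter_reports <- function(rows, config = report_filter_config()) {
  dt <- as.data.table(rows)
  required <- c("case_id", "drug", "event", "qualification", "drug_role",
                "version")
  miss <- setdiff(required, names(dt))
  if (length(miss) > 0L) {
    stop(input_error(sprintf("report table is missing column(s): %s",
                             paste(miss, collapse = ", "))))
  }
  counts <- integer(4)
  n0 <- nrow(dt)
  dt <- dt[as.character(qualification) %in% config$qualification_whitelist]
  counts[1] <- n0 - nrow(dt); n0 <- nrow(dt)
  dt <- dt[as.character(drug_role) %in% config$drug_role_whitelist]
  counts[2] <- n0 - nrow(dt); n0 <- nrow(dt)
  dt <- dt[sort(dt[, .I[version == max(version)], by = case_id]$V1)]
  counts[3] <- n0 - nrow(dt); n0 <- nrow(dt)
  dt <- dt[!tolower(event) %in% config$event_blacklist]
  counts[4] <- n0 - nrow(dt)
  setattr(dt, "removal_counts",
          setNames(counts, c("qualification", "drug_role", "case_version",
                             "event_blacklist")))
  dt[]
}

#' Aggregate a filtered report table into contingency counts
#'
#' All counts are over distinct case ids, not rows: `N` distinct reports,
#' `n_drug` reports mentioning each drug, `n_event` reports mentioning each
#' event, `n_pair` reports mentioning both.
#'
#' @param rows filtered report table.
#' @return a `contingency_counts` object.
#' @export
aggregate_counts <- function(rows) {
  dt <- as.data.table(rows)
  N <- uniqueN(dt$case_id)
  n_drug <- dt[, .(nj = uniqueN(case_id)), by = drug]
  n_event <- dt[, .(ni = uniqueN(case_id)), by = event]
  n_pair <- dt[, .(nij = uniqueN(case_id)), by = .(drug, event)]
  structure(list(N = N, n_drug = n_drug, n_event = n_event, n_pair = n_pair),
            class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat(sprintf("contingency counts: %d reports, %d drugs, %d events, %d pairs\n",
              x$N, nrow(x$n_drug), nrow(x$n_event), nrow(x$n_pair)))
  invisible(x)
}

#' One-sided likelihood-ratio statistic for a drug-event pair
#'
#' Vectorised over its arguments. Returns 0 whenever the observed co-mention
#' count does not exceed its expectation (under-reporting is not a signal);
#' `0 * log(0)` is taken as 0.
#'
#' @param nij reports mentioning both drug and event.
#' @param ni reports mentioning the event (event marginal).
#' @param nj reports mentioning the drug (drug marginal).
#' @param N total distinct reports.
#' @return non-negative numeric vector.
#' @export
llr <- function(nij, ni, nj, N) {
  if (any(nj < 1) || any(nij < 0) || any(nij > pmin(ni, nj)) ||
      any(pmin(ni, nj) > N)) {
    stop(input_error("llr: need 0 <= nij <= min(ni, nj) <= N and nj >= 1"))
  }
  E <- ni * nj / N
  xlogx <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  out <- xlogx(nij, E) + xlogx(nj - nij, nj - E)
  ifelse(nij <= E, 0, out)
}

#' Monte-Carlo critical value for the per-drug maximum LLR
#'
#' Simulates `n_sims` null datasets by reallocating the drug's `nj` reports
#' across all events multinomially with probabilities proportional to the
#' event marginals, takes the maximum LLR over events in each, and returns
#' the empirical (1 - alpha) quantile (inverse-ECDF) of that max-LLR sample.
#' Deterministic given `seed`.
#'
#' @param nj the drug's report count.
#' @param event_marginals named or unnamed vector of event marginal counts
#'   `ni` (all events, not only those co-mentioned with the drug).
#' @param N total distinct reports.
#' @param alpha significance level in (0,1).
#' @param n_sims number of null simulations (>= 1).
#' @param seed integer seed.
#' @return non-negative critical value.
#' @export
mc_critical_value <- function(nj, event_marginals, N, alpha = 0.05,
                              n_sims = 1000L, seed = 1L) {
  stopifnot(n_sims >= 1L, alpha > 0, alpha < 1, nj >= 1)
  ni <- as.numeric(event_marginals)
  if (length(ni) <= 1L) return(0) # single event: every null max-LLR is 0
  p <- ni / sum(ni)
  maxs <- withr::with_seed(seed, {
    x <- rmultinom(n_sims, size = nj, prob = p) # n_events x n_sims
    lm <- matrix(llr(pmin(as.vector(x), ni), rep(ni, n_sims), nj, N),
                 nrow = length(ni))
    apply(lm, 2L, max)
  })
  unname(quantile(maxs, probs = 1 - alpha, type = 1, names = FALSE))
}

#' Detect significant drug-adverse-event pairs
#'
#' For each drug a Monte-Carlo critical value of the maximum LLR is computed
#' with a child seed derived from `(seed, drug id)` — results are therefore
#' independent of drug processing order — and every event whose LLR exceeds
#' it is flagged. Within a drug, results are sorted by LLR descending.
#'
#' @param counts a [aggregate_counts()] result.
#' @param alpha per-drug family-wise level (default 0.05).
#' @param n_sims Monte-Carlo simulations per drug (default 1000).
#' @param seed master seed.
#' @param drugs optional character vector restricting detection to these
#'   drugs (their critical values still use the full event marginals).
#' @return data.table of signal results: `drug`, `event`, counts, `llr`,
#'   `critical_value`, `significant`.
#' @export
detect_signals <- function(counts, alpha = 0.05, n_sims = 1000L, seed = 1L,
                           drugs = NULL) {
  stopifnot(inherits(counts, "contingency_counts"))
  empty <- data.table(drug = character(0), event = character(0),
                      nij = integer(0), ni = integer(0), nj = integer(0),
                      N = integer(0), llr = numeric(0),
                      critical_value = numeric(0), significant = logical(0))
  if (counts$N == 0L || nrow(counts$n_pair) == 0L) return(empty)
  pair <- merge(counts$n_pair, counts$n_drug, by = "drug")
  pair <- merge(pair, counts$n_event, by = "event")
  if (!is.null(drugs)) pair <- pair[drug %in% drugs]
  if (nrow(pair) == 0L) return(empty)
  pair[, N := counts$N]
  pair[, llr := llr(nij, ni, nj, N)]
  marg <- setNames(counts$n_event$ni, counts$n_event$event)
  cv <- vapply(sort(unique(pair$drug)), function(d) {
    mc_critical_value(counts$n_drug[drug == d, nj], marg, counts$N,
                      alpha = alpha, n_sims = n_sims,
                      seed = derive_seed(seed, d))
  }, numeric(1))
  pair[, critical_value := cv[drug]]
  pair[, significant := llr > critical_value]
  setorderv(pair, c("drug", "llr", "event"), order = c(1L, -1L, 1L))
  setcolorder(pair, c("drug", "event", "nij", "ni", "nj", "N", "llr",
                      "critical_value", "significant"))
  pair[]
}
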