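#' Disease ontology: loading and evidence propagation
#'
#' The disease ontology is a DAG over term identifiers with child-to-parent
#' `is_a` edges (a term may have several parents). A designated subset of
#' nodes are therapeutic areas: evidence asserted at a term propagates to all
#' of its ancestors up to and including its therapeutic area(s), so a target
#' associated with a specific disease is also (indirectly) associated with
#' every more general term. A configured generic root is excluded from
#' propagation entirely.
#'
#' @name disease_ontology
NULL

new_ontology_graph <- function(nodes, labels, parents, therapeutic_areas,
                               root_ids) {
  structure(list(nodes = nodes, labels = labels, parents = parents,
                 therapeutic_areas = therapeutic_areas, root_ids = root_ids),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology graph: %d terms, %d is_a edges, %d therapeutic areas\n",
              length(x$nodes), sum(lengths(x$parents)),
              length(x$therapeutic_areas)))
  invisible(x)
}

# Parse the [Term] stanzas of an OBO 1.2/1.4 document: id:, name:, is_a:
# (with optional '! label' comment). All other relation types are ignored.
parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); cur <- list(is_a = character(0)); next
    }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; next } # [Typedef] etc.
    if (is.null(cur)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_a:", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$is_a <- c(cur$is_a, tgt)
    }
  }
  flush()
  terms
}

# DFS that either certifies acyclicity or names one directed cycle
find_cycle <- function(nodes, parents) {
  color <- setNames(rep(0L, length(nodes)), nodes) # 0 white, 1 grey, 2 black
  stack_path <- character(0)
  cycle <- NULL
  visit <- function(u) {
    if (!is.null(cycle)) return()
    color[u] <<- 1L
    stack_path <<- c(stack_path, u)
    for (p in parents[[u]]) {
      if (!p %in% nodes) next
      if (color[p] == 1L) {
        i <- match(p, stack_path)
        cycle <<- c(stack_path[i:length(stack_path)], p)
        return()
      }
      if (color[p] == 0L) visit(p)
      if (!is.null(cycle)) return()
    }
    color[u] <<- 2L
    stack_path <<- stack_path[-length(stack_path)]
  }
  for (n in nodes) if (color[n] == 0L) { visit(n); if (!is.null(cycle)) break }
  cycle
}

#' Load a disease ontology as a validated DAG
#'
#' Accepts either an OBO file (only `[Term]`, `id:`, `name:`, `is_a:` stanzas
#' are read; other relation types are ignored) or a two-column `child<TAB>parent`
#' edge table.
#'
#' @param doc path to an `.obo` file or to a TSV edge table, or a
#'   data.frame/data.table with columns `child`, `parent`.
#' @param therapeutic_area_ids term ids designated as therapeutic areas;
#'   propagation stops at (and includes) these.
#' @param root_ids optional generic root term ids excluded from propagation.
#' @return an `ontology_graph`.
#' @export
load_ontology <- function(doc, therapeutic_area_ids, root_ids = character(0)) {
  if (is.character(doc) && length(doc) == 1L) {
    if (!file.exists(doc)) stop(input_error(sprintf("ontology file not found: %s", doc)))
    if (grepl("\\.obo$", doc)) {
      terms <- parse_obo(doc)
      if (length(terms) == 0L) stop(schema_error("no [Term] stanzas in OBO file"))
      nodes <- vapply(terms, `[[`, character(1), "id")
      labels <- setNames(vapply(terms, function(t) t$name %||% t$id,
                                character(1)), nodes)
      parents <- setNames(lapply(terms, `[[`, "is_a"), nodes)
    } else {
      edges <- fread(doc, header = FALSE, sep = "\t",
                     col.names = c("child", "parent"), colClasses = "character")
      return(load_ontology(edges, therapeutic_area_ids, root_ids))
    }
  } else {
    edges <- as.data.table(doc)
    if (!all(c("child", "parent") %in% names(edges))) {
      setnames(edges, seq_len(2L), c("child", "parent"))
    }
    nodes <- sort(unique(c(edges$child, edges$parent)))
    labels <- setNames(nodes, nodes)
    parents <- setNames(lapply(nodes, function(n) edges$parent[edges$child == n]),
                        nodes)
  }
  # drop unknown is_a targets (OBO files may reference terms outside scope)
  parents <- lapply(parents, function(p) p[p %in% nodes])
  missing_ta <- setdiff(therapeutic_area_ids, nodes)
  if (length(missing_ta) > 0L) {
    stop(schema_error(sprintf("unknown therapeutic-area id(s): %s",
                              paste(missing_ta, collapse = ", "))))
  }
  cyc <- find_cycle(nodes, parents)
  if (!is.null(cyc)) {
    stop(schema_error(sprintf("ontology is not acyclic; cycle: %s",
                              paste(cyc, collapse = " -> "))))
  }
  new_ontology_graph(nodes, labels, parents,
                     unique(therapeutic_area_ids), unique(root_ids))
}

#' Ancestors of a term under the propagation rules
#'
#' All terms reachable from `term` via parent (`is_a`) edges, excluding any
#' configured generic root, and not continuing above a therapeutic-area node
#' (therapeutic areas are included but their parents are not traversed).
#'
#' @param graph an `ontology_graph`.
#' @param term a term id present in the graph.
#' @param include_self also include `term` itself.
#' @return character vector of ancestor ids (unordered set semantics).
#' @export
ancestors <- function(graph, term, include_self = FALSE) {
  if (!term %in% graph$nodes) {
    stop(input_error(sprintf("unknown ontology term: %s", term)))
  }
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (u in frontier) {
      # propagation stops at (and includes) therapeutic areas: never traverse
      # above one, even when the walk starts there
      if (u %in% graph$therapeutic_areas) next
      if (u %in% graph$root_ids) next
      for (p in graph$parents[[u]]) {
        if (p %in% graph$root_ids) next
        if (!p %in% seen && p != term) { seen <- c(seen, p); nxt <- c(nxt, p) }
      }
    }
    frontier <- nxt
  }
  if (include_self) unique(c(term, seen)) else seen
}

#' Expand evidence across the ontology
#'
#' Each evidence row is emitted once at its asserted disease (`direct = TRUE`)
#' and once at every ancestor (`direct = FALSE`); within one (evidence,
#' ancestor) pair the record appears exactly once even when the ancestor is
#' reachable by several paths. Rows whose disease id is not in the graph are
#' diverted to a rejects attribute, not fatal.
#'
#' @param graph an `ontology_graph`.
#' @param evidence evidence table from [evidence_table()] (any data.table
#'   with `disease_id` and an `evidence_id` column works).
#' @return data.table of emissions: the input columns with `disease_id`
#'   replaced by the emission node, plus `asserted_disease_id` and a `direct`
#'   flag. Attribute `rejects` holds the unresolvable rows.
#' @export
expand_evidence <- function(graph, evidence) {
  ev <- as.data.table(evidence)
  resolvable <- ev$disease_id %in% graph$nodes
  rejects <- ev[!resolvable]
  ev <- ev[resolvable]
  if (nrow(ev) == 0L) {
    out <- copy(ev)
    out[, `:=`(asserted_disease_id = character(0), direct = logical(0))]
    setattr(out, "rejects", rejects)
    return(out)
  }
  anc <- lapply(setNames(nm = unique(ev$disease_id)),
                function(d) ancestors(graph, d, include_self = FALSE))
  pieces <- lapply(seq_len(nrow(ev)), function(i) {
    d <- ev$disease_id[i]
    nodes <- c(d, anc[[d]])
    out <- ev[rep(i, length(nodes))]
    out[, asserted_disease_id := d]
    out[, disease_id := nodes]
    out[, direct := c(TRUE, rep(FALSE, length(nodes) - 1L))]
    out
  })
  out <- rbindlist(pieces)
  setattr(out, "rejects", rejects)
  out[]
}

#' @importFrom data.table setattr
NULL
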