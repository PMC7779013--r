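# shared in-code fixtures: tiny graphs, conforming records, random generators

`%||%` <- function(a, b) if (is.null(a)) b else a

# C -> B -> A, A a therapeutic area (smallest propagation chain)
chain_graph <- function() {
  load_ontology(data.frame(child = c("EFO_0000003", "EFO_0000002"),
                           parent = c("EFO_0000002", "EFO_0000001")),
                therapeutic_area_ids = "EFO_0000001")
}

# D -> {B, C} -> A: two paths from D to A
diamond_graph <- function() {
  load_ontology(data.frame(child = c("EFO_0000004", "EFO_0000004",
                                     "EFO_0000002", "EFO_0000003"),
                           parent = c("EFO_0000002", "EFO_0000003",
                                      "EFO_0000001", "EFO_0000001")),
                therapeutic_area_ids = "EFO_0000001")
}

minimal_record <- function(target_id = "ENSG00000157764",
                           disease_id = "EFO_0000270",
                           datasource_id = "eva",
                           datatype_id = "genetic_association",
                           resource_score = 0.7, ...) {
  list(target_id = target_id, disease_id = disease_id,
       datasource_id = datasource_id, datatype_id = datatype_id,
       score_payload = c(list(resource_score = resource_score), list(...)))
}

# random schema-conforming record (property-style generation)
random_conforming_record <- function() {
  src <- sample(c("eva", "europepmc", "expression_atlas", "phenodigm"), 1L)
  minimal_record(
    target_id = sprintf("ENSG%011d", sample.int(1e6, 1L)),
    disease_id = sprintf("EFO_%07d", sample.int(1e6, 1L)),
    datasource_id = src,
    datatype_id = sample(c("genetic_association", "somatic_mutation",
                           "known_drug", "affected_pathway", "rna_expression",
                           "literature", "animal_model"), 1L),
    resource_score = round(runif(1), 6))
}

# random DAG as child->parent edges over ranked nodes (edges to earlier ranks
# only); node 1.. n_ta are therapeutic areas with no parents
random_dag_edges <- function(n_nodes = 20L, max_parents = 3L, n_ta = 2L) {
  ids <- sprintf("T_%04d", seq_len(n_nodes))
  pieces <- lapply((n_ta + 1L):n_nodes, function(i) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    data.frame(child = ids[i], parent = sample(ids[seq_len(i - 1L)], k))
  })
  edges <- do.call(rbind, pieces)
  present <- unique(c(edges$child, edges$parent)) # a TA never sampled as a
  list(edges = edges, ids = intersect(ids, present), # parent has no node
       tas = intersect(ids[seq_len(n_ta)], present))
}

# independent oracle: recursive DFS transitive closure honouring the same
# stop-at-therapeutic-area / exclude-root rules as ancestors()
oracle_ancestors <- function(edges, tas, roots, term) {
  parents_of <- function(x) edges$parent[edges$child == x]
  seen <- new.env(parent = emptyenv())
  walk <- function(x) {
    if (x %in% tas || x %in% roots) return(invisible())
    for (p in parents_of(x)) {
      if (p %in% roots) next
      if (!is.null(seen[[p]])) next
      seen[[p]] <- TRUE
      walk(p)
    }
  }
  walk(term)
  setdiff(ls(seen), term)
}

# independent direct-summation oracle for the harmonic sum
oracle_harmonic <- function(scores, cap) {
  s <- sort(scores, decreasing = TRUE)
  total <- 0
  for (i in seq_len(min(length(s), cap))) total <- total + s[i] / i^2
  total
}

# independent nested-loop contingency counter over distinct cases
oracle_counts <- function(rows) {
  cases <- unique(rows$case_id)
  drugs <- unique(rows$drug)
  events <- unique(rows$event)
  has <- function(cond) vapply(cases, function(cs) any(cond(rows[rows$case_id == cs, ])), logical(1))
  n_drug <- vapply(drugs, function(d) sum(has(function(r) d %in% r$drug)), integer(1) + 0)
  n_event <- vapply(events, function(e) sum(has(function(r) e %in% r$event)), integer(1) + 0)
  pair <- list()
  for (d in drugs) for (e in events) {
    cnt <- sum(has(function(r) any(r$drug == d & r$event == e)))
    if (cnt > 0) pair[[paste(d, e, sep = "|")]] <- cnt
  }
  list(N = length(cases), n_drug = n_drug, n_event = n_event, n_pair = pair)
}
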