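# Gene-ontology overrepresentation. Plain one-sided Fisher (hypergeometric
# upper tail) per term against the analysis universe, plus the elim
# decorrelation scheme: terms are visited bottom-up through the ontology
# DAG and the genes of terms significant at `alpha` are removed from all
# of their ancestors before the ancestors are tested. Annotations are used
# as given (pre-propagated along the true path by the caller or the
# annotation source); no multiple-testing correction is applied across
# terms, matching the convention of reporting raw term p-values.

#' Fisher overrepresentation test per GO term
#'
#' One-sided hypergeometric upper-tail p-value per term: the probability
#' of at least the observed number of annotated genes in the study set,
#' drawing `|set|` genes from the universe. Terms with fewer than
#' `min_hits` study-set genes are filtered from the report; terms with
#' zero universe annotation are skipped.
#'
#' @param gene_set character vector of study genes (subset of `universe`):
#'   the tested gene background is the analysis universe, not the genome.
#' @param universe character vector of all genes considered.
#' @param annotations data frame (`gene_id`, `term_id`).
#' @param min_hits minimum study-set genes annotated to a reported term
#'   (default 5).
#' @param term_names optional named character vector of term names.
#' @return data frame (`term_id`, `term_name`, `annotated_in_universe`,
#'   `significant_in_set`, `expected`, `p_value`, `members`) ordered by
#'   p-value; `expected = |set| * annotated / |universe|`.
#' @export
fisher_enrich <- function(gene_set, universe, annotations, min_hits = 5,
                          term_names = NULL) {
  gene_set <- unique(gene_set); universe <- unique(universe)
  out_set <- setdiff(gene_set, universe)
  if (length(out_set) > 0)
    stop("gene_set gene not in universe: ", out_set[1], call. = FALSE)
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  terms <- split(ann$gene_id, ann$term_id)
  n_univ <- length(universe); n_set <- length(gene_set)
  rows <- lapply(names(terms), function(tt) {
    annotated <- terms[[tt]]
    k_univ <- length(annotated)
    if (k_univ == 0) return(NULL)
    hits <- intersect(annotated, gene_set)
    k <- length(hits)
    p <- stats::phyper(k - 1, k_univ, n_univ - k_univ, n_set,
                       lower.tail = FALSE)
    data.frame(term_id = tt,
               term_name = if (!is.null(term_names) && tt %in% names(term_names))
                 term_names[[tt]] else NA_character_,
               annotated_in_universe = k_univ, significant_in_set = k,
               expected = n_set * k_univ / n_univ, p_value = p,
               members = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(0), term_name = character(0),
                      annotated_in_universe = integer(0),
                      significant_in_set = integer(0), expected = numeric(0),
                      p_value = numeric(0), members = character(0)))
  res <- res[res$significant_in_set >= min_hits, , drop = FALSE]
  res <- res[order(res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}

topo_sort_bottom_up <- function(terms, edges) {
  # children before parents; edges: data.frame(child, parent)
  children_of <- split(edges$child, edges$parent)
  n_unvisited_children <- vapply(terms, function(tt)
    length(children_of[[tt]]), integer(1))
  order <- character(0)
  ready <- terms[n_unvisited_children == 0]
  remaining <- n_unvisited_children
  parents_of <- split(edges$parent, edges$child)
  while (length(ready) > 0) {
    tt <- ready[1]; ready <- ready[-1]
    order <- c(order, tt)
    for (pp in parents_of[[tt]]) {
      remaining[pp] <- remaining[pp] - 1
      if (remaining[pp] == 0) ready <- c(ready, pp)
    }
  }
  if (length(order) != length(terms))
    stop("ontology DAG contains a cycle", call. = FALSE)
  order
}

ancestors_of <- function(term, parents_of) {
  seen <- character(0); queue <- parents_of[[term]]
  while (length(queue) > 0) {
    p <- queue[1]; queue <- queue[-1]
    if (p %in% seen) next
    seen <- c(seen, p)
    queue <- c(queue, parents_of[[p]])
  }
  seen
}

#' Elim decorrelation of GO enrichment results
#'
#' Bottom-up traversal of the ontology DAG: each term is tested by Fisher's
#' method after removing from its annotation the genes of its descendants
#' that were significant at `alpha`. A flat DAG (no edges) reduces to
#' [fisher_enrich()]; elimination can only weaken ancestor terms.
#'
#' @inheritParams fisher_enrich
#' @param dag_edges data frame (`child`, `parent`) of ontology edges; must
#'   be acyclic.
#' @param alpha significance level triggering elimination (default 0.05).
#' @return as [fisher_enrich()], with an extra `eliminated` column counting
#'   genes removed from each term before testing.
#' @export
elim_decorrelate <- function(gene_set, universe, annotations, dag_edges,
                             alpha = 0.05, min_hits = 5, term_names = NULL) {
  gene_set <- unique(gene_set); universe <- unique(universe)
  ann <- unique(annotations[annotations$gene_id %in% universe,
                            c("gene_id", "term_id")])
  terms <- sort(unique(c(ann$term_id, dag_edges$child, dag_edges$parent)))
  if (nrow(dag_edges) > 0) {
    dag_edges <- unique(dag_edges[, c("child", "parent")])
    visit_order <- topo_sort_bottom_up(terms, dag_edges)
    parents_of <- split(dag_edges$parent, dag_edges$child)
  } else {
    visit_order <- terms
    parents_of <- list()
  }
  term_genes <- split(ann$gene_id, ann$term_id)
  removed <- stats::setNames(vector("list", length(terms)), terms)
  n_univ <- length(universe); n_set <- length(gene_set)
  rows <- list()
  for (tt in visit_order) {
    annotated <- setdiff(term_genes[[tt]], removed[[tt]])
    k_univ <- length(annotated)
    if (k_univ == 0 && is.null(term_genes[[tt]])) next
    hits <- intersect(annotated, gene_set)
    k <- length(hits)
    p <- if (k_univ == 0) 1 else
      stats::phyper(k - 1, k_univ, n_univ - k_univ, n_set, lower.tail = FALSE)
    rows[[tt]] <- data.frame(
      term_id = tt,
      term_name = if (!is.null(term_names) && tt %in% names(term_names))
        term_names[[tt]] else NA_character_,
      annotated_in_universe = k_univ, significant_in_set = k,
      expected = n_set * k_univ / n_univ, p_value = p,
      eliminated = length(removed[[tt]]),
      members = paste(sort(hits), collapse = ","),
      stringsAsFactors = FALSE)
    if (p < alpha && k_univ > 0) {
      for (anc in ancestors_of(tt, parents_of))
        removed[[anc]] <- union(removed[[anc]], annotated)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(0), term_name = character(0),
                      annotated_in_universe = integer(0),
                      significant_in_set = integer(0), expected = numeric(0),
                      p_value = numeric(0), eliminated = integer(0),
                      members = character(0)))
  res <- res[res$significant_in_set >= min_hits, , drop = FALSE]
  res <- res[order(res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}
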