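## Functional-context summaries computed locally: hypergeometric annotation
## over-representation with BH correction, and high-confidence
## interaction-network neighborhoods over a scored edge list.

#' Hypergeometric annotation over-representation
#'
#' For each term with at least one hit, the upper-tail probability of
#' drawing `k` or more annotated proteins in a query of size `n` from a
#' background of `M` proteins of which `K` carry the term:
#' `p = P(X >= k)` for `X ~ Hypergeometric(M, K, n)`. BH q-values are
#' computed across all tested terms (one annotation namespace, one
#' correction). One-tailed over-representation only.
#'
#' @param query character vector of protein symbols; must be non-empty and a
#'   subset of the annotation background.
#' @param annotations an [annotation_map()].
#' @return data.frame ordered by p-value with columns `term`, `k`, `n`,
#'   `K`, `M`, `p`, `q`.
#' @export
term_enrichment <- function(query, annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  query <- unique(as.character(query))
  if (!length(query)) value_error("empty query")
  stray <- setdiff(query, annotations$background)
  if (length(stray)) {
    value_error(paste0("query proteins outside background: ",
                       paste(utils::head(stray, 5L), collapse = ", "),
                       if (length(stray) > 5L) ", ..."))
  }
  M <- length(annotations$background)
  n <- length(query)
  rows <- lapply(names(annotations$sets), function(tm) {
    members <- annotations$sets[[tm]]
    K <- length(members)
    k <- length(intersect(members, query))
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, M = M, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), M = integer(), p = numeric(),
                      q = numeric()))
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' High-confidence interaction subnetwork
#'
#' Keeps the edges whose combined confidence score is strictly above
#' `threshold` and whose endpoints both belong to the query protein set,
#' and returns the induced connected components sorted by size (ties by the
#' lexicographically smallest member). Proteins without any retained edge do
#' not appear: an interaction neighborhood is by definition connected.
#'
#' @param proteins character vector of query protein symbols.
#' @param edges data.frame with columns `a`, `b`, `score`
#'   (see [read_edges()]).
#' @param threshold confidence cutoff in `[0, 1)`; the default 0.9 keeps
#'   only high-confidence interactions (score > 0.9, strict).
#' @return a `subnetwork` list: `nodes`, `edges` (filtered), `components`
#'   (list of sorted member vectors), `threshold`.
#' @export
high_confidence_subnetwork <- function(proteins, edges, threshold = 0.9) {
  if (!(threshold >= 0 && threshold < 1)) {
    config_error("threshold must lie in [0, 1)")
  }
  proteins <- unique(as.character(proteins))
  keep <- edges$score > threshold & edges$a %in% proteins &
    edges$b %in% proteins
  kept <- edges[keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (!nrow(kept)) {
    return(structure(list(nodes = character(), edges = kept,
                          components = list(), threshold = threshold),
                     class = "subnetwork"))
  }
  g <- igraph::graph_from_data_frame(kept[c("a", "b")], directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  o <- order(-lengths(members),
             vapply(members, `[[`, character(1L), 1L))
  members <- unname(members[o])
  structure(list(nodes = sort(unique(c(kept$a, kept$b))), edges = kept,
                 components = members, threshold = threshold),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork: score >", x$threshold, "-", length(x$nodes), "nodes,",
      nrow(x$edges), "edges,", length(x$components), "component(s)\n")
  if (length(x$components)) {
    cat("component sizes:", paste(lengths(x$components), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-component annotation enrichment
#'
#' Runs [term_enrichment()] on the node set of every connected component of
#' a subnetwork. Component nodes are first intersected with the annotation
#' background (an unannotated protein cannot enter the hypergeometric
#' model); components with no annotated node yield an empty result.
#'
#' @param subnetwork a `subnetwork` from [high_confidence_subnetwork()].
#' @param annotations an [annotation_map()].
#' @param min_size skip components with fewer nodes, default 2.
#' @return named list (`component_1`, `component_2`, ...) of enrichment
#'   data.frames, in component-size order.
#' @export
component_enrichment <- function(subnetwork, annotations, min_size = 2L) {
  stopifnot(inherits(subnetwork, "subnetwork"))
  comps <- subnetwork$components
  if (!length(comps)) return(stats::setNames(list(), character()))
  out <- lapply(seq_along(comps), function(i) {
    nodes <- comps[[i]]
    if (length(nodes) < min_size) return(NULL)
    query <- intersect(nodes, annotations$background)
    if (!length(query)) return(NULL)
    term_enrichment(query, annotations)
  })
  names(out) <- paste0("component_", seq_along(comps))
  out[!vapply(out, is.null, logical(1L))]
}
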