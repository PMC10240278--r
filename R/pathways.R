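# Pathway ranking: relative node betweenness centrality scores plus
# hypergeometric over-representation against the all-pathway compound
# background.

#' Read a pathway set from JSON
#'
#' The file holds an array of pathways, each with a `name`, `nodes`
#' (objects with `id` and `type`, type `compound` or `reaction`) and
#' `edges` (pairs of node ids). Graphs are undirected; reaction nodes shape
#' the topology but are never over-representation hits.
#'
#' @param path JSON file path; default is the packaged synthetic pathway
#'   fixture (a small stand-in for a mouse metabolic pathway database).
#' @return An object of class `pathway_set`: named list of pathways (each
#'   with `graph`, `nodes`, `compounds`) plus a `background` attribute, the
#'   union of all participating compounds.
#' @export
read_pathways <- function(path = system.file("extdata", "pathways_synthetic.json",
                            package = "zonalipid"
                          )) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  names_ <- vapply(raw, `[[`, character(1), "name")
  if (anyDuplicated(names_)) {
    stop("duplicate pathway names: ", paste(names_[duplicated(names_)], collapse = ", "),
      call. = FALSE
    )
  }
  pw <- lapply(raw, function(p) {
    nodes <- tibble::tibble(
      id = vapply(p$nodes, `[[`, character(1), "id"),
      type = vapply(p$nodes, `[[`, character(1), "type")
    )
    stopifnot(all(nodes$type %in% c("compound", "reaction")))
    edges <- do.call(rbind, lapply(p$edges, unlist))
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges),
      directed = FALSE,
      vertices = as.data.frame(nodes)
    )
    compounds <- nodes$id[nodes$type == "compound"]
    if (!length(compounds)) stop("pathway without compounds: ", p$name, call. = FALSE)
    list(graph = g, nodes = nodes, compounds = compounds)
  })
  names(pw) <- names_
  structure(pw,
    background = sort(unique(unlist(lapply(pw, `[[`, "compounds")))),
    class = "pathway_set"
  )
}

#' @export
print.pathway_set <- function(x, ...) {
  cat("<pathway_set> ", length(x), " pathways, background of ",
    length(attr(x, "background")), " compounds\n",
    sep = ""
  )
  invisible(x)
}

#' Relative node betweenness centrality
#'
#' Betweenness `g(v) = sum over pairs s != v != t of sigma_st(v) / sigma_st`
#' (unordered pairs), divided by the maximum possible `(N-1)(N-2)/2`.
#' Disconnected graphs are normalised per connected component (with the
#' component size as N); components with fewer than 3 nodes score 0.
#'
#' @param graph An igraph object (treated as undirected).
#' @return Named numeric vector in `[0, 1]` over vertices.
#' @export
relative_betweenness <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  out <- stats::setNames(numeric(n), igraph::V(graph)$name)
  if (n < 3) return(out)
  comp <- igraph::components(graph)
  bc <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  for (ci in seq_len(comp$no)) {
    nc <- comp$csize[ci]
    idx <- comp$membership == ci
    norm <- (nc - 1) * (nc - 2) / 2
    out[idx] <- if (norm > 0) bc[idx] / norm else 0
  }
  out
}

#' Centrality-weighted pathway score
#'
#' The fraction of total compound-node relative betweenness carried by the
#' hit compounds: `sum(centrality[hits]) / sum(centrality[compounds])`,
#' with 0/0 defined as 0. Reaction nodes shape the graph but never count as
#' hits.
#'
#' @param pathway One element of a [read_pathways()] set (or the set plus a
#'   pathway name).
#' @param hits Character vector of hit compound ids.
#' @param name When `pathway` is a `pathway_set`, the pathway name.
#' @return Score in `[0, 1]`.
#' @export
pathway_score <- function(pathway, hits, name = NULL) {
  if (inherits(pathway, "pathway_set")) {
    if (is.null(name) || !name %in% names(pathway)) {
      stop("unknown pathway: ", name, call. = FALSE)
    }
    pathway <- pathway[[name]]
  }
  bc <- relative_betweenness(pathway$graph)
  comp <- pathway$compounds
  denom <- sum(bc[comp])
  num <- sum(bc[intersect(hits, comp)])
  if (denom == 0) return(0)
  num / denom
}

#' Hypergeometric over-representation p value
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` pathway
#' compounds when `n` hits are drawn from a background of `N` compounds of
#' which `K` belong to the pathway.
#'
#' @param k Overlap count. @param K Pathway size. @param n Hit-list size.
#' @param N Background size.
#' @return Exact p value in (0, 1].
#' @export
hypergeometric_ora <- function(k, K, n, N) {
  if (!(k >= 0 && k <= min(K, n) && K <= N && n <= N)) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Map lipids to pathway compound identifiers
#'
#' Sum-composition species are mapped at class level (every TG to the
#' generic `TG` compound node, etc.), since pathway databases hold
#' species-generic lipid nodes.
#'
#' @param library Lipid library tibble.
#' @return Tibble `lipid_id`, `compound_id`.
#' @export
lipid_compound_map <- function(library) {
  tibble::tibble(
    lipid_id = library$id,
    compound_id = library$subclass
  )
}

#' Rank pathways for a significant-lipid list
#'
#' Computes the centrality-weighted score and hypergeometric
#' over-representation p value of every pathway for the compounds mapped
#' from the significant lipids. The background is the union of all pathway
#' compounds; results are sorted by descending score, then ascending ORA p,
#' then name.
#'
#' @param pathway_set A [read_pathways()] object.
#' @param lipids Character vector of significant lipid ids (or a
#'   `zonation_test` tibble, from which significant lipids are taken).
#' @param mapping Tibble `lipid_id`, `compound_id` (see
#'   [lipid_compound_map()]).
#' @return A tibble of class `pathway_ranking`: `pathway`, `score`, `ora_p`,
#'   `k`, `K`, `n`, `N`, `hits` (list column of matched compound ids).
#' @export
rank_pathways <- function(pathway_set, lipids, mapping) {
  stopifnot(inherits(pathway_set, "pathway_set"))
  if (inherits(lipids, "zonation_test")) {
    lipids <- lipids$lipid_id[lipids$significant]
  }
  background <- attr(pathway_set, "background")
  hit_comp <- sort(unique(mapping$compound_id[mapping$lipid_id %in% lipids]))
  hit_comp <- intersect(hit_comp, background)
  if (!length(hit_comp)) {
    warning("empty hit list; all scores are 0 and ORA p values 1")
  }
  n <- length(hit_comp)
  N <- length(background)
  rows <- lapply(names(pathway_set), function(nm) {
    p <- pathway_set[[nm]]
    hits <- intersect(hit_comp, p$compounds)
    tibble::tibble(
      pathway = nm,
      score = pathway_score(p, hit_comp),
      ora_p = hypergeometric_ora(length(hits), length(p$compounds), n, N),
      k = length(hits), K = length(p$compounds), n = n, N = N,
      hits = list(hits)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$ora_p, .data$pathway)
  class(out) <- c("pathway_ranking", class(out))
  out
}
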