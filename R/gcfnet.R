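## Similarity networks, gene cluster families (connected components),
## and novelty scoring against reference clusters.

#' Test whether BGC ids are reference (MIBiG-style) accessions
#'
#' @param ids Character vector of BGC ids.
#' @param pattern Regular expression identifying reference accessions.
#' @return Logical vector.
#' @export
is_reference_id <- function(ids, pattern = "^BGC\\d{7}") {
  grepl(pattern, as.character(ids))
}

#' Build a distance-thresholded BGC similarity network
#'
#' Retains edges with distance less than or equal to the cutoff
#' (inclusive); isolated nodes are kept as singletons.
#'
#' @param edges `data.frame` with columns `a`, `b`, `distance`.
#' @param nodes Optional character vector of node ids; must cover every
#'   edge endpoint if supplied. When `NULL`, nodes are the edge endpoints.
#' @param cutoff Distance cutoff in (0, 1); default 0.5.
#' @param bgc_class Optional class label attached to the network.
#' @param reference_pattern Regular expression marking reference nodes.
#' @return A `bgc_network` object: nodes, reference flags, retained
#'   edges, cutoff, class.
#' @export
build_network <- function(edges, nodes = NULL, cutoff = 0.5,
                          bgc_class = NULL,
                          reference_pattern = "^BGC\\d{7}") {
  check_that(cutoff > 0 && cutoff < 1, "cutoff must lie in (0, 1)")
  edges <- canonicalize_edges(edges)
  endpoints <- unique(c(edges$a, edges$b))
  if (is.null(nodes)) {
    nodes <- endpoints
  } else {
    nodes <- unique(as.character(nodes))
    unknown <- setdiff(endpoints, nodes)
    check_that(length(unknown) == 0L,
               "edge references node absent from node list: %s", unknown[1])
  }
  nodes <- c_sort(nodes)
  kept <- edges[edges$distance <= cutoff, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(nodes = nodes,
                 is_reference = is_reference_id(nodes, reference_pattern),
                 edges = kept, cutoff = cutoff, bgc_class = bgc_class),
            class = "bgc_network")
}

#' @export
print.bgc_network <- function(x, ...) {
  cat(sprintf("BGC similarity network%s: %d nodes (%d reference), %d edges (cutoff %.2f)\n",
              if (is.null(x$bgc_class)) "" else paste0(" [", x$bgc_class, "]"),
              length(x$nodes), sum(x$is_reference), nrow(x$edges), x$cutoff))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("a", "b")], directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Derive gene cluster families as connected components
#'
#' Every node (including singletons) is assigned to exactly one family;
#' the family id is the lexicographically smallest member id, so labels
#' are deterministic and invariant to input order.
#'
#' @param net A [build_network()] object.
#' @return `data.frame` with `bgc_id`, `family_id`.
#' @export
connected_components <- function(net) {
  if (length(net$nodes) == 0L) {
    return(data.frame(bgc_id = character(), family_id = character(),
                      stringsAsFactors = FALSE))
  }
  comp <- igraph::components(as_igraph(net))$membership
  comp <- comp[net$nodes]
  fam_id <- stats::ave(net$nodes, comp,
                       FUN = function(v) v[c_order(v)][1])
  out <- data.frame(bgc_id = net$nodes, family_id = fam_id,
                    stringsAsFactors = FALSE)
  out <- out[c_order(out$family_id, out$bgc_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify families as putatively known or novel
#'
#' A family is putatively known when it contains at least one reference
#' cluster, putatively novel otherwise. Reference ids absent from the
#' membership are ignored (logged).
#'
#' @param membership `data.frame` from [connected_components()].
#' @param reference_ids Character vector of reference node ids.
#' @return Family-level `data.frame`: `family_id`, `n_members`,
#'   `is_known`.
#' @export
classify_novelty <- function(membership, reference_ids) {
  extras <- setdiff(reference_ids, membership$bgc_id)
  if (length(extras)) {
    gcf_log(sprintf("%d reference id(s) not present in network; ignored",
                    length(extras)))
  }
  is_ref <- membership$bgc_id %in% reference_ids
  fam <- factor(membership$family_id,
                levels = c_sort(unique(membership$family_id)))
  data.frame(family_id = levels(fam),
             n_members = as.integer(tabulate(fam, nlevels(fam))),
             is_known = as.logical(tapply(is_ref, fam, any)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of novel families
#'
#' @param families Output of [classify_novelty()].
#' @return Proportion of families with `is_known = FALSE`.
#' @export
novel_fraction <- function(families) {
  check_that(nrow(families) > 0L, "no families supplied")
  mean(!families$is_known)
}

#' Per-BGC distance to the closest reference cluster
#'
#' For each non-reference node, the minimum distance over retained direct
#' edges linking it to a reference node; the sentinel (default 0.51, just
#' above the cutoff) when no such edge exists. Only direct edges count:
#' pairs absent from a BiG-SCAPE network file have unknown distance above
#' the cutoff, which is exactly the sentinel's meaning.
#'
#' @param net A [build_network()] object.
#' @param reference_ids Reference node ids; defaults to the network's
#'   pattern-flagged reference nodes.
#' @param sentinel Sentinel distance, strictly greater than the cutoff.
#' @return `data.frame` with `bgc_id`, `distance_to_reference` for every
#'   non-reference node.
#' @export
min_reference_distance <- function(net, reference_ids = NULL,
                                   sentinel = 0.51) {
  if (is.null(reference_ids)) reference_ids <- net$nodes[net$is_reference]
  check_that(sentinel > net$cutoff, "sentinel must exceed the cutoff")
  query <- setdiff(net$nodes, reference_ids)
  score <- stats::setNames(rep(sentinel, length(query)), query)
  e <- net$edges
  ref_a <- e$a %in% reference_ids
  ref_b <- e$b %in% reference_ids
  touch <- data.frame(
    bgc = c(e$b[ref_a], e$a[ref_b]),
    d = c(e$distance[ref_a], e$distance[ref_b]),
    stringsAsFactors = FALSE)
  touch <- touch[!(touch$bgc %in% reference_ids), , drop = FALSE]
  if (nrow(touch)) {
    m <- tapply(touch$d, touch$bgc, min)
    score[names(m)] <- pmin(score[names(m)], m)
  }
  data.frame(bgc_id = query, distance_to_reference = unname(score),
             stringsAsFactors = FALSE)
}

#' Per-sample minimum novelty for one biosynthetic class
#'
#' For each sample, the minimum distance-to-closest-reference over that
#' sample's BGCs of the given class. Samples with no BGC of the class are
#' absent from the output (never zero-filled).
#'
#' @param scores Output of [min_reference_distance()].
#' @param inventory BGC inventory (`bgc_id`, `sample_id`, `bgc_class`).
#' @param bgc_class Class to evaluate.
#' @return `data.frame` with `sample_id`, `min_novelty`.
#' @export
sample_min_novelty <- function(scores, inventory, bgc_class) {
  inv <- inventory[inventory$bgc_class == bgc_class, , drop = FALSE]
  merged <- merge(inv, scores, by = "bgc_id")
  if (nrow(merged) == 0L) {
    return(data.frame(sample_id = character(), min_novelty = numeric(),
                      stringsAsFactors = FALSE))
  }
  sid <- factor(merged$sample_id, levels = c_sort(unique(merged$sample_id)))
  m <- tapply(merged$distance_to_reference, sid, min)
  data.frame(sample_id = names(m), min_novelty = unname(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Community structure of a similarity network
#'
#' Greedy modularity maximization on the unweighted retained-edge graph,
#' for reporting and display parity only — families are always defined by
#' connected components, never by communities. An edgeless network yields
#' one community per node with Q = 0.
#'
#' @param net A [build_network()] object.
#' @return List with `membership` (`data.frame`: `bgc_id`, `community`)
#'   and `modularity` (Q).
#' @export
modularity_communities <- function(net) {
  if (nrow(net$edges) == 0L) {
    return(list(membership = data.frame(bgc_id = net$nodes,
                                        community = seq_along(net$nodes),
                                        stringsAsFactors = FALSE),
                modularity = 0))
  }
  g <- as_igraph(net)
  fc <- igraph::cluster_fast_greedy(igraph::simplify(g))
  mem <- igraph::membership(fc)
  mem <- mem[net$nodes]
  list(membership = data.frame(bgc_id = net$nodes,
                               community = as.integer(mem),
                               stringsAsFactors = FALSE),
       modularity = igraph::modularity(g, mem))
}
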