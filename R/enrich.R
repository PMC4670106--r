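#' Geneset collection
#'
#' A named list of genesets (character vectors of gene ids) with an
#' optional term hierarchy (child -> parent edges forming a DAG), as read
#' from GMT files or built by [simulate_genesets()]. Member ids are not
#' required to lie in any particular universe; the intersection with the
#' universe is taken at test time.
#'
#' @param sets named list of character vectors; names must be unique.
#' @param name collection identifier (e.g. "GO-BP", "canonical-pathways").
#' @param hierarchy optional data frame with columns `child` and `parent`
#'   referring to set names; must be acyclic.
#' @return list of class `"geneset_collection"`.
#' @export
geneset_collection <- function(sets, name = "collection", hierarchy = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 &&
      (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == "")))
    stop("schema error: sets must have unique non-empty names")
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (!is.null(hierarchy)) {
    stopifnot(all(c("child", "parent") %in% names(hierarchy)))
    .topo_order(hierarchy)  # errors on cycles
  }
  structure(list(name = name, sets = sets, hierarchy = hierarchy),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  if (length(x$sets) == 0) {
    cat(sprintf("Geneset collection '%s': empty\n", x$name))
    return(invisible(x))
  }
  sz <- lengths(x$sets)
  cat(sprintf("Geneset collection '%s': %d sets (sizes %d-%d)%s\n",
              x$name, length(x$sets), min(sz), max(sz),
              if (is.null(x$hierarchy)) "" else
                sprintf(", %d hierarchy edges", nrow(x$hierarchy))))
  invisible(x)
}

# Topological order of set names in a child->parent edge list; stops on
# cycles. Returns names ordered so every child precedes its parents.
.topo_order <- function(edges) {
  nodes <- unique(c(edges$child, edges$parent))
  out_edges <- split(edges$parent, factor(edges$child, levels = nodes))
  indeg <- table(factor(edges$parent, levels = nodes))
  queue <- nodes[indeg == 0]  # leaves of the parent-ward orientation
  order <- character(0)
  indeg <- as.vector(indeg); names(indeg) <- nodes
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in out_edges[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < length(nodes))
    stop("input error: cyclic hierarchy")
  order
}

#' Propagate annotations up a term hierarchy (true-path rule)
#'
#' Every term's membership becomes the union of its own members and those
#' of all its descendants, so a gene annotated to a specific term also
#' counts for every ancestor.
#'
#' @param collection a [geneset_collection()] with a hierarchy.
#' @return the collection with propagated memberships (hierarchy kept).
#' @export
propagate_annotations <- function(collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  h <- collection$hierarchy
  if (is.null(h) || nrow(h) == 0) return(collection)
  ord <- .topo_order(h)  # children before parents
  sets <- collection$sets
  for (nm in ord) {
    if (is.null(sets[[nm]])) sets[[nm]] <- character(0)
  }
  parents <- split(h$parent, h$child)
  for (child in ord) {
    for (p in parents[[child]]) {
      sets[[p]] <- union(sets[[p]], sets[[child]])
    }
  }
  geneset_collection(sets, name = collection$name, hierarchy = h)
}

#' Nested prefix subsets of a ranked gene list
#'
#' Subsets of sizes `step, 2*step, ...` up to the largest multiple of
#' `step` not exceeding the list length, plus the full list when its
#' length is not a multiple. Subsets are strictly nested prefixes.
#'
#' @param ranked character vector, most significant gene first.
#' @param step subset-size increment (default 25).
#' @return named list of character vectors; names are the subset sizes.
#' @export
nested_subsets <- function(ranked, step = 25) {
  if (length(ranked) == 0) stop("input error: empty ranked list")
  if (step < 1) stop("configuration error: step must be >= 1")
  if (anyDuplicated(ranked)) stop("input error: duplicated gene ids in ranked list")
  n <- length(ranked)
  sizes <- seq_len(n %/% step) * step
  if (length(sizes) == 0 || sizes[length(sizes)] < n) sizes <- c(sizes, n)
  stats::setNames(lapply(sizes, function(k) ranked[seq_len(k)]), sizes)
}

#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= overlap)` for
#' `X ~ Hypergeometric(N = |universe|, K = |geneset & universe|,
#' n = |subset|)`. Identical to a one-sided Fisher exact test on the 2x2
#' table; one implementation serves both the pathway and GO paths.
#'
#' @param subset character vector of genes, must lie inside `universe`.
#' @param geneset character vector; intersected with `universe` before
#'   testing.
#' @param universe character vector of background genes.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_enrich <- function(subset, geneset, universe) {
  if (length(universe) == 0) stop("input error: empty universe")
  if (!all(subset %in% universe))
    stop("input error: subset must be contained in the universe")
  eff <- intersect(geneset, universe)
  if (length(eff) == 0) {
    warning("hypergeom_enrich: geneset has no members in the universe; p = 1")
    return(1)
  }
  N <- length(unique(universe)); K <- length(eff); n <- length(unique(subset))
  x <- length(intersect(subset, eff))
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO-style enrichment with true-path propagation
#'
#' Propagates annotations up the collection's hierarchy (see
#' [propagate_annotations()]) and then applies the one-sided
#' hypergeometric test to every term. With a flat hierarchy this reduces
#' exactly to [hypergeom_enrich()] per set.
#'
#' @inheritParams hypergeom_enrich
#' @param collection a [geneset_collection()], optionally with hierarchy.
#' @return named numeric vector of per-term p-values.
#' @export
go_enrich <- function(subset, collection, universe) {
  stopifnot(inherits(collection, "geneset_collection"))
  collection <- propagate_annotations(collection)
  vapply(collection$sets, function(s)
    suppressWarnings(hypergeom_enrich(subset, s, universe)), numeric(1))
}

#' Enrichment profile of a collection over nested ranked subsets
#'
#' Tests every geneset against every nested subset and records the matrix
#' of `-log10 p` (sets x subset sizes), the raw p-values, a significance
#' mask (`p < mask_alpha`, the display rule), per-set best p-values, and a
#' BH adjustment across sets within each subset-size column. When the
#' collection carries a hierarchy, annotations are propagated first.
#'
#' @param collection a [geneset_collection()].
#' @param subsets list of strictly nested prefix subsets from
#'   [nested_subsets()].
#' @param universe background gene ids (the confidently detected genes).
#' @param mask_alpha display-mask threshold (default 0.05).
#' @return object of class `"enrich_profile"`: list with `neglogp`, `p`,
#'   `mask`, `padj`, `best_p`, `subset_sizes`, `collection`, `mask_alpha`.
#' @export
enrichment_profile <- function(collection, subsets, universe, mask_alpha = 0.05) {
  stopifnot(inherits(collection, "geneset_collection"))
  sizes <- lengths(subsets)
  if (length(sizes) == 0) stop("input error: no subsets")
  if (is.unsorted(sizes, strictly = TRUE))
    stop("input error: subsets must be strictly nested")
  full <- subsets[[length(subsets)]]
  for (i in seq_along(subsets))
    if (!identical(subsets[[i]], full[seq_len(sizes[i])]))
      stop("input error: subsets must be nested prefixes of the ranked list")
  if (!all(full %in% universe))
    stop("input error: ranked genes must be contained in the universe")
  collection <- propagate_annotations(collection)
  universe <- unique(universe)
  N <- length(universe)
  # rank of each universe gene in the full ranked prefix (NA if unranked)
  rank_of <- stats::setNames(rep(NA_integer_, N), universe)
  rank_of[full] <- seq_along(full)

  set_names <- names(collection$sets)
  p <- matrix(1, length(set_names), length(sizes),
              dimnames = list(set_names, sizes))
  for (s in seq_along(set_names)) {
    eff <- intersect(collection$sets[[s]], universe)
    K <- length(eff)
    if (K == 0) {
      warning("enrichment_profile: set '", set_names[s],
              "' has no members in the universe; p = 1")
      next
    }
    pos <- sort(rank_of[eff][!is.na(rank_of[eff])])
    x <- findInterval(sizes, pos)  # overlap with each prefix
    p[s, ] <- stats::phyper(x - 1, K, N - K, sizes, lower.tail = FALSE)
  }
  padj <- if (nrow(p) > 0) apply(p, 2L, bh_adjust) else p
  if (is.null(dim(padj))) padj <- matrix(padj, nrow = nrow(p), dimnames = dimnames(p))
  best_p <- if (nrow(p) > 0) apply(p, 1L, min) else stats::setNames(numeric(0), character(0))
  structure(list(neglogp = -log10(p), p = p, mask = p < mask_alpha,
                 padj = padj, best_p = best_p,
                 subset_sizes = unname(sizes), collection = collection$name,
                 mask_alpha = mask_alpha),
            class = "enrich_profile")
}

#' @export
print.enrich_profile <- function(x, ...) {
  cat(sprintf(
    "Enrichment profile '%s': %d sets x %d subset sizes (%d-%d); %d sets significant at p < %g\n",
    x$collection, nrow(x$p), length(x$subset_sizes), min(x$subset_sizes),
    max(x$subset_sizes), sum(x$best_p < x$mask_alpha), x$mask_alpha))
  best <- sort(x$best_p)[seq_len(min(5, length(x$best_p)))]
  for (nm in names(best))
    cat(sprintf("  %-40s best p = %.3g at n = %d\n", nm, x$best_p[nm],
                x$subset_sizes[which.min(x$p[nm, ])]))
  invisible(x)
}

#' Rank genesets by their most significant enrichment
#'
#' Orders sets by the smallest p-value attained at any subset size (ties
#' broken by set name) and returns the first `top_k`.
#'
#' @param profile an [enrichment_profile()] result.
#' @param top_k number of sets to return (default 15).
#' @return character vector of set names.
#' @export
rank_genesets <- function(profile, top_k = 15) {
  stopifnot(inherits(profile, "enrich_profile"))
  if (top_k < 1) stop("configuration error: top_k must be >= 1")
  ord <- order(profile$best_p, names(profile$best_p))
  names(profile$best_p)[ord][seq_len(min(top_k, length(ord)))]
}
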