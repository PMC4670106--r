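#' Integrate enrichment profiles and cluster into functional groups
#'
#' Takes one enrichment profile per collection, selects each collection's
#' `top_k` genesets by best p-value, concatenates the selected rows into a
#' single matrix (genesets x subset sizes), zeroes cells that fail the
#' display mask (`p >= mask_alpha`; set `use_mask = FALSE` to cluster on
#' raw `-log10 p`), normalizes each row by its sum, and clusters rows by
#' agglomerative hierarchical clustering with Ward linkage on Euclidean
#' distances. The tree is cut into `n_groups` groups. Deterministic given
#' the input order.
#'
#' @param profiles list of [enrichment_profile()] objects sharing identical
#'   subset-size columns.
#' @param top_k sets kept per collection (default 15).
#' @param n_groups number of groups to cut the tree into (default 5).
#' @param use_mask zero out non-significant cells before normalizing?
#' @return object of class `"clustergram"`: list with `matrix`
#'   (row-normalized, input row order), `hclust`, `groups` (named integer
#'   vector), `row_order` (dendrogram order), `subset_sizes`, `dropped`
#'   (names of all-zero rows removed).
#' @export
integrate_and_cluster <- function(profiles, top_k = 15, n_groups = 5,
                                  use_mask = TRUE) {
  if (inherits(profiles, "enrich_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0,
            all(vapply(profiles, inherits, logical(1), "enrich_profile")))
  sizes <- profiles[[1]]$subset_sizes
  for (pr in profiles)
    if (!identical(pr$subset_sizes, sizes))
      stop("input error: profiles have mismatched subset-size columns")
  rows <- list()
  for (pr in profiles) {
    sel <- rank_genesets(pr, top_k)
    m <- pr$neglogp[sel, , drop = FALSE]
    if (use_mask) m <- m * pr$mask[sel, , drop = FALSE]
    rownames(m) <- paste0(pr$collection, ":", sel)
    rows[[length(rows) + 1L]] <- m
  }
  mat <- do.call(rbind, rows)
  rs <- rowSums(mat)
  dropped <- rownames(mat)[rs == 0]
  if (length(dropped)) {
    warning(sprintf("integrate_and_cluster: dropped %d all-zero rows",
                    length(dropped)))
    mat <- mat[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  if (nrow(mat) < 2)
    stop("input error: fewer than two non-zero rows to cluster")
  mat <- mat / rs
  hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
  k <- min(n_groups, nrow(mat))
  groups <- stats::cutree(hc, k = k)
  structure(list(matrix = mat, hclust = hc, groups = groups,
                 row_order = hc$order, subset_sizes = sizes,
                 n_groups = k, use_mask = use_mask, dropped = dropped),
            class = "clustergram")
}

#' @export
print.clustergram <- function(x, ...) {
  cat(sprintf("Clustergram: %d genesets x %d subset sizes, %d groups\n",
              nrow(x$matrix), ncol(x$matrix), x$n_groups))
  for (g in sort(unique(x$groups[x$row_order]))) {
    members <- names(x$groups)[x$groups == g]
    cat(sprintf("  group %s (%d sets): %s%s\n", LETTERS[g], length(members),
                paste(utils::head(members, 3), collapse = ", "),
                if (length(members) > 3) ", ..." else ""))
  }
  invisible(x)
}

#' Heatmap of a clustergram
#'
#' Base-graphics image of the row-normalized enrichment matrix in
#' dendrogram order, with group letters along the left margin.
#'
#' @param x a [integrate_and_cluster()] result.
#' @param col color ramp.
#' @param ... ignored.
#' @export
plot.clustergram <- function(x, col = grDevices::hcl.colors(64, "YlOrRd",
                                                            rev = TRUE), ...) {
  m <- x$matrix[x$row_order, , drop = FALSE]
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(x = seq_along(x$subset_sizes), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = col, axes = FALSE, xlab = "top-n genes", ylab = "")
  graphics::axis(1, at = seq_along(x$subset_sizes), labels = x$subset_sizes,
                 las = 2, cex.axis = 0.6)
  labs <- sprintf("[%s] %s", LETTERS[x$groups[x$row_order]],
                  rownames(m))
  graphics::axis(2, at = rev(seq_len(nrow(m))), labels = labs, las = 2,
                 cex.axis = 0.5, tick = FALSE)
  invisible(x)
}
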