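# Independent oracles used across tests. Each re-derives the quantity it
# checks from first principles, without touching the package's code path.

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
enum_hypergeom <- function(N, K, n, x) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked) >= x)
  mean(hits)
}

# Benjamini-Hochberg by the definition: padj_i = min over j with p_j >= p_i
# of m * p_(j) / rank(j), capped at 1.
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force Ward agglomeration: at each step merge the pair of clusters
# whose centroid-based Ward cost sqrt(2ab/(a+b) * ||cA - cB||^2) is
# smallest, recomputing from cluster members every time.
bf_ward <- function(x) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      A <- clusters[[i]]; B <- clusters[[j]]
      cA <- colMeans(x[A, , drop = FALSE]); cB <- colMeans(x[B, , drop = FALSE])
      h <- sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
                  sum((cA - cB)^2))
      if (h < best[1]) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    merges[s, ] <- sort(c(ids[i], ids[j]))
    heights[s] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- s
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merges, height = heights)
}

# Partition of 1..n implied by cutting a brute-force Ward run at k groups
# (re-running agglomeration and stopping after n - k merges).
bf_ward_cut <- function(x, k) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  for (s in seq_len(n - k)) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      A <- clusters[[i]]; B <- clusters[[j]]
      cA <- colMeans(x[A, , drop = FALSE]); cB <- colMeans(x[B, , drop = FALSE])
      h <- sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
                  sum((cA - cB)^2))
      if (h < best[1]) best <- c(h, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  labels <- integer(n)
  for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
  labels
}

# Same-partition comparison up to label renaming.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Small labeled count matrix for toy tests.
toy_counts <- function(values, n_case, n_control, gene_ids = NULL) {
  m <- matrix(values, ncol = n_case + n_control, byrow = TRUE)
  rownames(m) <- gene_ids %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- c(sprintf("case%02d", seq_len(n_case)),
                   sprintf("ctrl%02d", seq_len(n_control)))
  storage.mode(m) <- "integer"
  m
}

toy_condition <- function(n_case, n_control) {
  rep(c("HD", "control"), c(n_case, n_control))
}

# Minimal sample table for nb_wald_test.
toy_samples <- function(n_case, n_control, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  data.frame(
    sample_id = c(sprintf("case%02d", seq_len(n_case)),
                  sprintf("ctrl%02d", seq_len(n_control))),
    condition = toy_condition(n_case, n_control),
    age_of_death = sample(40:85, n, replace = TRUE),
    rin = round(runif(n, 6, 9), 1),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
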