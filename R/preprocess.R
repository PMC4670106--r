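#' Filter genes with low signal in both groups
#'
#' A gene is retained when it has nonzero counts in at least half of the
#' case samples (rounded up) OR at least half of the control samples; it is
#' removed only when both groups fall below that mark. Retention on either
#' group's evidence deliberately preserves genes expressed almost
#' exclusively in one condition, which are among the strongest signals in
#' diseased brain.
#'
#' @param counts non-negative integer gene x sample matrix with dimnames.
#' @param condition character/factor of group labels per column, exactly
#'   two levels, no missing values.
#' @return list with `counts` (retained rows) and `removed` (character
#'   vector of removed gene ids).
#' @export
filter_low_signal <- function(counts, condition) {
  .check_counts(counts)
  condition <- .check_condition(condition, ncol(counts))
  keep <- rep(FALSE, nrow(counts))
  for (g in levels(condition)) {
    cols <- condition == g
    need <- ceiling(sum(cols) / 2)
    keep <- keep | rowSums(counts[, cols, drop = FALSE] > 0) >= need
  }
  list(counts = counts[keep, , drop = FALSE],
       removed = rownames(counts)[!keep])
}

#' Winsorize extreme counts per gene within each group
#'
#' For each gene and each condition group, counts above the Tukey fence
#' `Q3 + k * IQR` (linear-interpolation quartiles, R type 7) are replaced by
#' the ceiling of the fence. No value is ever increased and the result
#' stays integer, so the within-group median is unchanged.
#'
#' @inheritParams filter_low_signal
#' @param k fence multiplier, positive (default 3, an "extreme outlier"
#'   fence).
#' @param qtype quantile type passed to [stats::quantile()] (default 7,
#'   linear interpolation).
#' @return integer matrix of the same shape; attribute `cells_trimmed`
#'   holds the number of replaced cells.
#' @export
trim_outlier_counts <- function(counts, condition, k = 3, qtype = 7) {
  .check_counts(counts)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("configuration error: k must be a positive real")
  condition <- .check_condition(condition, ncol(counts))
  out <- counts
  trimmed <- 0L
  for (g in levels(condition)) {
    cols <- which(condition == g)
    block <- counts[, cols, drop = FALSE]
    qs <- apply(block, 1L, stats::quantile, probs = c(0.25, 0.75),
                type = qtype, names = FALSE)
    bound <- ceiling(qs[2L, ] + k * (qs[2L, ] - qs[1L, ]))
    over <- block > bound  # recycles bound down columns
    trimmed <- trimmed + sum(over)
    block[over] <- rep(bound, ncol(block))[over]
    out[, cols] <- block
  }
  storage.mode(out) <- "integer"
  if (trimmed > 0)
    message(sprintf("trim_outlier_counts: adjusted %d cells (k = %g)", trimmed, k))
  attr(out, "cells_trimmed") <- trimmed
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as the median, over reference
#' genes, of the ratio of the sample's count to the gene's geometric mean
#' across samples. Reference genes are those with strictly positive counts
#' in every sample (geometric mean > 0).
#'
#' @param counts non-negative gene x sample matrix.
#' @return positive numeric vector named by sample.
#' @export
size_factors <- function(counts) {
  .check_counts(counts, allow_real = TRUE)
  log_geo <- rowMeans(log(counts))
  ref <- is.finite(log_geo)
  if (!any(ref))
    stop("normalization error: no gene has nonzero counts in every sample; ",
         "cannot form the median-of-ratios reference set. Filter or merge ",
         "samples, or supply size factors explicitly.")
  sf <- apply(counts[ref, , drop = FALSE], 2L,
              function(cnt) exp(stats::median(log(cnt) - log_geo[ref])))
  names(sf) <- colnames(counts)
  sf
}

#' Divide counts by per-sample size factors
#'
#' @param counts gene x sample matrix.
#' @param sf size factors from [size_factors()]; computed if missing.
#' @return numeric matrix of normalized counts with attribute
#'   `size_factors`.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  stopifnot(length(sf) == ncol(counts), all(sf > 0))
  out <- sweep(counts, 2L, sf, "/")
  attr(out, "size_factors") <- sf
  out
}

#' Closed-form variance-stabilizing transform for NB counts
#'
#' Applies `g(x) = (2 / sqrt(alpha)) * asinh(sqrt(alpha * x))`, the exact
#' variance stabilizer for the quadratic mean-variance relation
#' `Var = mu + alpha * mu^2`. It is monotone increasing, `g(0) = 0`, and
#' tends to `2 * sqrt(x)` (the Poisson stabilizer) as `alpha -> 0`.
#'
#' @param x non-negative numeric vector or matrix (normalized counts).
#' @param alpha positive NB dispersion.
#' @return transformed values, same shape as `x`.
#' @export
vst_transform <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("configuration error: alpha must be a positive real")
  if (any(x < 0)) stop("vst_transform: values must be non-negative")
  (2 / sqrt(alpha)) * asinh(sqrt(alpha * x))
}

#' Estimate the NB dispersion alpha
#'
#' Per-gene estimates of alpha in `Var = mu + alpha * mu^2`, computed on
#' normalized counts conditional on the case/control group means.
#' `method = "mle"` maximizes the NB likelihood given the group-mean fit
#' ([MASS::theta.ml()]), falling back to the moment estimator where the
#' likelihood fit fails; `method = "moments"` uses the pooled within-group
#' variance directly. `shared = TRUE` returns a single alpha (the median of
#' the per-gene values), which keeps the closed-form VST exact.
#'
#' @param counts raw counts (gene x sample).
#' @param condition group labels per column.
#' @param sf size factors (computed if missing).
#' @param method `"mle"` or `"moments"`.
#' @param shared collapse to one shared alpha?
#' @param floor lower bound for alpha (default 1e-8).
#' @return numeric vector of length `nrow(counts)` (or length 1 when
#'   `shared = TRUE`).
#' @export
estimate_dispersion <- function(counts, condition, sf = size_factors(counts),
                                method = c("mle", "moments"),
                                shared = FALSE, floor = 1e-8) {
  method <- match.arg(method)
  condition <- .check_condition(condition, ncol(counts))
  yn <- sweep(counts, 2L, sf, "/")
  grp <- lapply(levels(condition), function(g) which(condition == g))
  m_grp <- vapply(grp, function(ix) rowMeans(yn[, ix, drop = FALSE]),
                  numeric(nrow(counts)))
  # pooled within-group variance of normalized counts
  ss <- 0; df <- 0
  for (k in seq_along(grp)) {
    ix <- grp[[k]]
    if (length(ix) > 1) {
      ss <- ss + rowSums((yn[, ix, drop = FALSE] - m_grp[, k])^2)
      df <- df + length(ix) - 1L
    }
  }
  vbar <- ss / max(df, 1L)
  mbar <- rowMeans(yn)
  alpha <- pmax((vbar - mbar) / mbar^2, floor)
  alpha[!is.finite(alpha)] <- floor
  if (method == "mle") {
    for (i in seq_len(nrow(counts))) {
      mu <- rep(0, ncol(counts))
      for (k in seq_along(grp)) mu[grp[[k]]] <- m_grp[i, k] * sf[grp[[k]]]
      if (all(mu <= 0) || all(counts[i, ] == 0)) next
      th <- tryCatch(
        suppressWarnings(MASS::theta.ml(counts[i, ], pmax(mu, 1e-8), limit = 50)),
        error = function(e) NA_real_)
      if (is.finite(th) && th > 0) alpha[i] <- max(1 / th, floor)
    }
  }
  if (shared) stats::median(alpha) else alpha
}

#' Run the full preprocessing contract
#'
#' Convenience wrapper: low-signal filter, per-group outlier winsorization,
#' median-of-ratios normalization and dispersion estimation.
#'
#' @inheritParams trim_outlier_counts
#' @param disp_method dispersion estimator, see [estimate_dispersion()].
#' @return list with `counts` (filtered + trimmed raw counts), `removed`,
#'   `size_factors`, `normalized`, `dispersion` (per-gene alpha),
#'   `vst` (VST-transformed normalized counts at the shared alpha) and
#'   `vst_alpha`.
#' @export
preprocess_counts <- function(counts, condition, k = 3,
                              disp_method = c("mle", "moments")) {
  disp_method <- match.arg(disp_method)
  flt <- filter_low_signal(counts, condition)
  if (length(flt$removed))
    message(sprintf("filter_low_signal: removed %d of %d genes",
                    length(flt$removed), nrow(counts)))
  trimmed <- trim_outlier_counts(flt$counts, condition, k = k)
  sf <- size_factors(trimmed)
  normalized <- normalize_counts(trimmed, sf)
  alpha <- estimate_dispersion(trimmed, condition, sf, method = disp_method)
  alpha_shared <- stats::median(alpha)
  list(counts = trimmed, removed = flt$removed, size_factors = sf,
       normalized = normalized, dispersion = alpha,
       vst = vst_transform(normalized, alpha_shared), vst_alpha = alpha_shared)
}

.check_counts <- function(counts, allow_real = FALSE) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample identifiers as dimnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample identifiers")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!allow_real && any(counts != round(counts)))
    stop("counts must be integers")
  invisible(counts)
}

.check_condition <- function(condition, n) {
  if (length(condition) != n)
    stop("labeling error: one group label per sample is required")
  if (anyNA(condition))
    stop("labeling error: sample with unknown group")
  condition <- factor(as.character(condition))
  if (nlevels(condition) != 2L)
    stop("labeling error: exactly two groups are required, got ",
         nlevels(condition))
  if (any(table(condition) == 0L)) stop("labeling error: empty group")
  condition
}
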