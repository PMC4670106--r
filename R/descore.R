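#' Differential Expression Score (DES)
#'
#' `DES = overall mean normalized counts x |log2 fold change| x
#' -log10(adjusted p-value)`. The score prioritizes genes that are at once
#' abundant, strongly changed and statistically secure, in contrast to a
#' pure significance ranking, which is dominated by low-abundance genes
#' expressed almost exclusively in one condition. Adjusted p-values below
#' `padj_floor` are clamped so underflowed p-values cannot produce an
#' infinite score.
#'
#' @param overall_mean non-negative mean normalized count(s).
#' @param lfc log2 fold change(s); the absolute value enters the score.
#' @param padj adjusted p-value(s) in `(0, 1]`.
#' @param padj_floor clamp for tiny adjusted p-values (default 1e-300).
#' @return non-negative numeric score(s).
#' @export
des_score <- function(overall_mean, lfc, padj, padj_floor = 1e-300) {
  if (any(overall_mean < 0, na.rm = TRUE))
    stop("input error: overall_mean must be non-negative")
  if (any(padj > 1, na.rm = TRUE))
    stop("input error: adjusted p-values must not exceed 1")
  padj <- pmax(padj, padj_floor)
  if (any(padj <= 0, na.rm = TRUE))
    stop("input error: adjusted p-values must be positive after clamping")
  overall_mean * abs(lfc) * (-log10(padj))
}

#' Rank a DE table by DES
#'
#' Adds a `des` column and returns the full table sorted by DES descending
#' (ties broken by gene id) with a `des_rank` column.
#'
#' @param table data frame with columns `gene_id`, `overall_mean`, `lfc`
#'   and `padj` (e.g. a [nb_wald_test()] result).
#' @param padj_floor see [des_score()].
#' @param use_nominal score on the nominal p-value column `p` instead of
#'   `padj` (sensitivity analysis only).
#' @return the table with `des` and `des_rank` columns, sorted by rank.
#' @export
rank_by_des <- function(table, padj_floor = 1e-300, use_nominal = FALSE) {
  need <- c("gene_id", "overall_mean", "lfc", if (use_nominal) "p" else "padj")
  if (!all(need %in% names(table)))
    stop("input error: table lacks columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  pcol <- if (use_nominal) table$p else table$padj
  table$des <- des_score(table$overall_mean, table$lfc, pcol, padj_floor)
  ord <- order(-table$des, table$gene_id)
  out <- table[ord, , drop = FALSE]
  out$des_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("des_table", "data.frame")
  out
}

#' @export
print.des_table <- function(x, n = 10L, ...) {
  cat(sprintf("DES-ranked gene table: %d genes (top DES = %.4g)\n",
              nrow(x), if (nrow(x)) x$des[1] else NA_real_))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}

#' Fraction of up-regulated genes in a sliding window over a ranked list
#'
#' At rank position `x` the profile reports the fraction of genes with
#' positive log2 fold change among ranks `(x, x + window]` of the
#' significance-ranked list; trailing windows truncate to the genes
#' available.
#'
#' @param lfc numeric log2 fold changes in ranked order (most significant
#'   first).
#' @param window window width in genes (default 100).
#' @param step step between window start positions (default 1).
#' @return data frame with `position` (0-based window start) and
#'   `frac_up`.
#' @export
updown_profile <- function(lfc, window = 100, step = 1) {
  if (window < 1) stop("configuration error: window must be >= 1")
  if (step < 1) stop("configuration error: step must be >= 1")
  n <- length(lfc)
  if (window > n) stop("window exceeds the list length")
  up <- cumsum(c(0, lfc > 0))
  pos <- seq(0L, n - 1L, by = step)
  hi <- pmin(pos + window, n)
  data.frame(position = pos,
             frac_up = (up[hi + 1L] - up[pos + 1L]) / (hi - pos))
}

#' Biotype composition of a gene list
#'
#' @param genes character vector of gene ids.
#' @param biotypes named character vector (gene id -> biotype) or a data
#'   frame with columns `gene_id` and `biotype`. Genes absent from the map
#'   fall into an `"unknown"` bucket (with a message).
#' @return named numeric vector of proportions, summing to 1, sorted
#'   decreasing.
#' @export
biotype_composition <- function(genes, biotypes) {
  if (is.data.frame(biotypes)) {
    stopifnot(all(c("gene_id", "biotype") %in% names(biotypes)))
    biotypes <- stats::setNames(as.character(biotypes$biotype), biotypes$gene_id)
  }
  bt <- unname(biotypes[genes])
  n_missing <- sum(is.na(bt))
  if (n_missing > 0) {
    message(sprintf("biotype_composition: %d genes without a biotype -> 'unknown'",
                    n_missing))
    bt[is.na(bt)] <- "unknown"
  }
  sort(c(table(bt) / length(bt)), decreasing = TRUE)
}

#' Row-max normalization for heatmap display
#'
#' Divides every row by its maximum so the largest value per row is 1;
#' all-zero rows pass through unchanged (with a message). Row-wise argmax
#' and within-row ordering are preserved.
#'
#' @param mat non-negative numeric matrix.
#' @return matrix with values in `[0, 1]`.
#' @export
rowmax_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0)) stop("rowmax_normalize: values must be non-negative")
  mx <- apply(mat, 1L, max)
  zero <- mx == 0
  if (any(zero))
    message(sprintf("rowmax_normalize: %d all-zero rows passed through", sum(zero)))
  mx[zero] <- 1
  mat / mx
}
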