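#' Build the DE design from a sample table
#'
#' Encodes condition (reference level: control), age at death binned into
#' 0-45, 46-60, 61-75 and 76+ years, and a dichotomized RNA quality
#' indicator (RIN > 7). Factor levels with no samples are dropped; a
#' covariate that is constant across samples is excluded from the model
#' (with a message) rather than producing a singular design.
#'
#' @param samples data frame with columns `condition` (values `HD` /
#'   `control`), `age_of_death` and `rin`.
#' @param age_breaks increasing breakpoints for the age bins; the last bin
#'   is open-ended.
#' @param rin_cut threshold for the high-quality indicator.
#' @return list with `model_matrix` (samples x coefficients), `condition`
#'   (factor) and `terms` (character vector of covariates retained).
#' @export
de_design <- function(samples, age_breaks = c(0, 45, 60, 75, Inf), rin_cut = 7) {
  stopifnot(all(c("condition", "age_of_death", "rin") %in% names(samples)))
  condition <- factor(samples$condition, levels = c("control", "HD"))
  if (anyNA(condition)) stop("labeling error: condition must be HD or control")
  labs <- paste0(age_breaks[-length(age_breaks)] + c(0, rep(1, length(age_breaks) - 2)),
                 "-", c(age_breaks[-c(1, length(age_breaks))], ""))
  labs[length(labs)] <- paste0(age_breaks[length(age_breaks) - 1] + 1, "+")
  age_bin <- cut(samples$age_of_death, breaks = age_breaks, labels = labs,
                 include.lowest = TRUE)
  if (anyNA(age_bin)) stop("design error: age outside the binning range")
  rin_high <- factor(samples$rin > rin_cut, levels = c(FALSE, TRUE),
                     labels = c("low", "high"))
  df <- data.frame(condition = condition, age_bin = droplevels(age_bin),
                   rin_high = rin_high)
  terms <- "condition"
  for (v in c("age_bin", "rin_high")) {
    if (nlevels(droplevels(df[[v]])) > 1) terms <- c(terms, v)
    else message("de_design: covariate ", v, " is constant and was dropped")
  }
  X <- stats::model.matrix(stats::reformulate(terms), df)
  if (qr(X)$rank < ncol(X))
    stop("design error: collinear design matrix")
  list(model_matrix = X, condition = condition, terms = terms)
}

# One NB GLM with log link and fixed dispersion; Wald statistics for the
# coefficient in column `coef_ix` of X. SEs use the NB information at the
# fitted values (GLM dispersion fixed at 1).
.nb_fit <- function(y, X, offset, alpha, coef_ix = 2L) {
  fam <- MASS::negative.binomial(theta = 1 / max(alpha, 1e-8))
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$rank < ncol(X))
    return(c(beta = NA_real_, se = NA_real_, p = NA_real_))
  R <- qr.R(fit$qr)
  covp <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(covp)) return(c(beta = NA_real_, se = NA_real_, p = NA_real_))
  piv <- fit$qr$pivot
  cov <- matrix(NA_real_, ncol(X), ncol(X))
  cov[piv, piv] <- covp
  beta <- fit$coefficients[coef_ix]
  se <- sqrt(cov[coef_ix, coef_ix])
  z <- beta / se
  c(beta = unname(beta), se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Negative-binomial Wald differential expression
#'
#' Fits, per gene, an NB GLM with log link, `log(size factor)` offsets and
#' coefficients for condition plus the age-bin and RIN covariates of
#' [de_design()]. The condition coefficient is reported as a log2 fold
#' change (case vs control) with its standard error; the Wald p-value
#' compares coefficient / SE to a standard normal. Group means are
#' computed on normalized counts. P-values are BH-adjusted and genes with
#' adjusted p below `de_alpha` are flagged DE. Non-converged fits are
#' flagged with missing statistics and excluded from the FDR denominator.
#'
#' @param counts preprocessed integer gene x sample matrix.
#' @param samples sample table covering every column of `counts` (matched
#'   by `sample_id` when present, otherwise by position).
#' @param sf size factors; computed by [size_factors()] if missing.
#' @param dispersion per-gene alpha vector, a single shared alpha, or
#'   `NULL` to estimate via [estimate_dispersion()].
#' @param disp_method estimator used when `dispersion` is `NULL`.
#' @param de_alpha FDR threshold for the DE call (default 0.05).
#' @return A data frame of class `"de_table"` with columns `gene_id`,
#'   `overall_mean`, `case_mean`, `control_mean`, `lfc`, `se`, `p`, `padj`,
#'   `is_de`, in the input gene order.
#' @export
nb_wald_test <- function(counts, samples, sf = NULL, dispersion = NULL,
                         disp_method = c("mle", "moments"), de_alpha = 0.05) {
  .check_counts(counts)
  disp_method <- match.arg(disp_method)
  samples <- .align_samples(samples, colnames(counts))
  design <- de_design(samples)
  X <- design$model_matrix
  is_case <- design$condition == "HD"
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, design$condition, sf,
                                      method = disp_method)
  if (length(dispersion) == 1L) dispersion <- rep(dispersion, nrow(counts))
  stopifnot(length(dispersion) == nrow(counts))

  yn <- sweep(counts, 2L, sf, "/")
  off <- log(sf)
  ci <- which(colnames(X) == "conditionHD")
  res <- matrix(NA_real_, nrow(counts), 3L,
                dimnames = list(rownames(counts), c("beta", "se", "p")))
  for (i in seq_len(nrow(counts)))
    res[i, ] <- .nb_fit(counts[i, ], X, off, dispersion[i], coef_ix = ci)
  n_failed <- sum(is.na(res[, "p"]))
  if (n_failed > 0)
    warning(sprintf("nb_wald_test: %d gene fits did not converge; ",
                    n_failed), "their p-values are missing")
  out <- data.frame(
    gene_id = rownames(counts),
    overall_mean = rowMeans(yn),
    case_mean = rowMeans(yn[, is_case, drop = FALSE]),
    control_mean = rowMeans(yn[, !is_case, drop = FALSE]),
    lfc = res[, "beta"] / log(2),
    se = res[, "se"] / log(2),
    p = res[, "p"],
    stringsAsFactors = FALSE, row.names = NULL)
  out$padj <- bh_adjust(out$p)
  out$is_de <- !is.na(out$padj) & out$padj < de_alpha
  attr(out, "de_alpha") <- de_alpha
  attr(out, "dispersion") <- dispersion
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, n = 10L, ...) {
  cat(sprintf("NB-Wald differential expression: %d genes, %d DE at FDR < %g\n",
              nrow(x), sum(x$is_de, na.rm = TRUE),
              attr(x, "de_alpha") %||% 0.05))
  print.data.frame(utils::head(x[order(x$p), ], n), digits = 4)
  invisible(x)
}

#' @export
summary.de_table <- function(object, ...) {
  de <- object[object$is_de %in% TRUE, ]
  out <- list(n_genes = nrow(object), n_de = nrow(de),
              n_up = sum(de$lfc > 0), n_down = sum(de$lfc < 0),
              n_failed = sum(is.na(object$p)))
  cat(sprintf(
    "%d genes tested (%d fits failed); %d DE (%d up, %d down, %.1f%% up)\n",
    out$n_genes, out$n_failed, out$n_de, out$n_up, out$n_down,
    if (out$n_de > 0) 100 * out$n_up / out$n_de else NA_real_))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement. Missing values
#' propagate as missing and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("input error: p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("input error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Rank and extract the DE gene list
#'
#' Returns exactly the genes with `padj < threshold`, ordered by p
#' ascending with ties broken by |log2 fold change| descending and then by
#' gene id, so that the ranking is deterministic.
#'
#' @param table a `de_table`.
#' @param threshold FDR threshold (default 0.05).
#' @return character vector of gene ids, ranked by significance.
#' @export
call_de <- function(table, threshold = 0.05) {
  stopifnot(all(c("gene_id", "lfc", "p", "padj") %in% names(table)))
  hit <- !is.na(table$padj) & table$padj < threshold
  tb <- table[hit, , drop = FALSE]
  tb$gene_id[order(tb$p, -abs(tb$lfc), tb$gene_id)]
}

.align_samples <- function(samples, sample_ids) {
  if (!is.data.frame(samples)) stop("samples must be a data frame")
  if ("sample_id" %in% names(samples)) {
    ix <- match(sample_ids, samples$sample_id)
    if (anyNA(ix))
      stop("design error: samples missing from the sample table: ",
           paste(utils::head(sample_ids[is.na(ix)], 5), collapse = ", "))
    samples <- samples[ix, , drop = FALSE]
  } else if (nrow(samples) != length(sample_ids)) {
    stop("design error: sample table does not cover all count columns")
  }
  samples
}
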