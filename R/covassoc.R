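#' Per-gene association of transformed expression with a clinical covariate
#'
#' Ordinary least squares per gene: `expression ~ covariate + rin`. The
#' slope (beta) and two-sided t-test p-value for the covariate term are
#' reported, with BH adjustment across all tested genes. Clinical
#' covariates measured only in cases (CAG, onset, H-V scores) should be
#' passed with a case-only expression matrix.
#'
#' @param vst_expr numeric gene x sample matrix of variance-stabilized
#'   expression.
#' @param covariate numeric per-sample covariate (CAG, residual onset,
#'   H-V score, ...).
#' @param rin numeric per-sample RNA integrity number.
#' @return data frame of class `"assoc_table"` with columns `gene_id`,
#'   `beta`, `se`, `p`, `padj`.
#' @export
covariate_regression <- function(vst_expr, covariate, rin) {
  stopifnot(is.matrix(vst_expr))
  n <- ncol(vst_expr)
  if (length(covariate) != n || length(rin) != n)
    stop("association error: covariate and rin must have one value per sample")
  if (anyNA(covariate) || anyNA(rin))
    stop("association error: missing covariate values; subset samples first")
  if (n <= 3) stop("insufficient-data error: need more than 3 samples")
  X <- cbind(1, covariate = covariate, rin = rin)
  if (qr(X)$rank < 3L)
    stop("association error: covariate is constant or collinear with rin")
  XtXinv <- solve(crossprod(X))
  coefs <- XtXinv %*% crossprod(X, t(vst_expr))   # 3 x genes
  resid <- t(vst_expr) - X %*% coefs
  df <- n - 3L
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  beta <- coefs[2L, ]
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(gene_id = rownames(vst_expr), beta = unname(beta),
                    se = unname(se), p = unname(p),
                    padj = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' @export
print.assoc_table <- function(x, n = 10L, ...) {
  cat(sprintf("Covariate association: %d genes, %d at FDR < 0.05 (min padj %.3g)\n",
              nrow(x), sum(x$padj < 0.05, na.rm = TRUE), min(x$padj, na.rm = TRUE)))
  print.data.frame(utils::head(x[order(x$p), ], n), digits = 4)
  invisible(x)
}

#' Fit a log-linear onset-vs-CAG model
#'
#' Least-squares fit of `log(onset) ~ cag`, the standard functional form
#' for the decline of HD onset age with repeat length. Returns a
#' prediction function usable as the `model` argument of
#' [residual_onset()].
#'
#' @param onset ages at onset (years).
#' @param cag CAG repeat lengths.
#' @return function mapping CAG to predicted onset (years), with the fit
#'   coefficients attached as attribute `"coefficients"`.
#' @export
fit_onset_model <- function(onset, cag) {
  stopifnot(length(onset) == length(cag), all(onset > 0))
  fit <- stats::lm(log(onset) ~ cag)
  co <- stats::coef(fit)
  f <- function(cag) exp(co[[1]] + co[[2]] * cag)
  attr(f, "coefficients") <- co
  f
}

#' CAG-adjusted residual age at onset
#'
#' Residual = observed onset minus the onset predicted from CAG repeat
#' length. Published prediction coefficients are not bundled; supply your
#' own model, or leave `model = NULL` to fit the default log-linear model
#' ([fit_onset_model()]) on the data at hand, in which case the residuals
#' are centered near zero by construction.
#'
#' @param onset observed ages at onset (years).
#' @param cag CAG repeat lengths, same length.
#' @param model a function mapping CAG to predicted onset, or `NULL`.
#' @return numeric residuals (years).
#' @export
residual_onset <- function(onset, cag, model = NULL) {
  stopifnot(length(onset) == length(cag))
  if (is.null(model)) model <- fit_onset_model(onset, cag)
  if (!is.function(model))
    stop("configuration error: 'model' must be a function CAG -> predicted ",
         "onset (supply published coefficients wrapped in a function, or ",
         "NULL to fit a log-linear model on these data)")
  onset - model(cag)
}

#' Check DE calls for confounding by cortical involvement
#'
#' For each DE gene, fits (cases only) an NB GLM of raw counts on the H-V
#' cortical involvement score adjusting for RIN, with log size-factor
#' offsets, and BH-adjusts across the DE genes. The result is flagged
#' `confounded` when any gene reaches adjusted p < `alpha` - i.e. when the
#' DE signal could reflect cortical cell-loss severity rather than disease
#' state.
#'
#' @param counts integer gene x sample matrix, case samples only.
#' @param de_genes character vector of DE gene ids (subset of rownames).
#' @param hv_cortical numeric per-case cortical involvement score.
#' @param rin numeric per-case RIN.
#' @param sf size factors for the case samples (computed if `NULL`).
#' @param dispersion per-gene alpha for `de_genes` (scalar recycled);
#'   moment-estimated from the case samples if `NULL`.
#' @param alpha flag threshold (default 0.05).
#' @return list of class `"confound_check"`: `table` (an `assoc_table`
#'   for the DE genes) and `confounded` (logical flag).
#' @export
confound_check <- function(counts, de_genes, hv_cortical, rin, sf = NULL,
                           dispersion = NULL, alpha = 0.05) {
  .check_counts(counts)
  if (length(de_genes) == 0)
    return(structure(list(table = data.frame(gene_id = character(0),
                                             beta = numeric(0), se = numeric(0),
                                             p = numeric(0), padj = numeric(0)),
                          confounded = FALSE),
                     class = "confound_check"))
  if (!all(de_genes %in% rownames(counts)))
    stop("input error: de_genes must be a subset of the count matrix genes")
  n <- ncol(counts)
  if (length(hv_cortical) != n || length(rin) != n)
    stop("association error: hv_cortical and rin must have one value per sample")
  if (is.null(sf)) sf <- size_factors(counts)
  cnt <- counts[de_genes, , drop = FALSE]
  if (is.null(dispersion)) {
    yn <- sweep(cnt, 2L, sf, "/")
    m <- rowMeans(yn); v <- apply(yn, 1L, stats::var)
    dispersion <- pmax((v - m) / m^2, 1e-8)
    dispersion[!is.finite(dispersion)] <- 1e-8
  }
  if (length(dispersion) == 1L) dispersion <- rep(dispersion, length(de_genes))
  X <- cbind(`(Intercept)` = 1, hv_cortical = hv_cortical, rin = rin)
  if (qr(X)$rank < ncol(X))
    stop("association error: collinear covariates")
  off <- log(sf)
  res <- t(vapply(seq_along(de_genes), function(i)
    .nb_fit(cnt[i, ], X, off, dispersion[i], coef_ix = 2L), numeric(3)))
  out <- data.frame(gene_id = de_genes, beta = res[, 1] , se = res[, 2],
                    p = res[, 3], padj = bh_adjust(res[, 3]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("assoc_table", "data.frame")
  structure(list(table = out,
                 confounded = any(out$padj < alpha, na.rm = TRUE)),
            class = "confound_check")
}

#' @export
print.confound_check <- function(x, ...) {
  if (nrow(x$table) == 0) {
    cat("Confounding check: no DE genes supplied\n")
  } else {
    cat(sprintf(
      "Confounding check on %d DE genes: %s (min padj %.3g)\n",
      nrow(x$table),
      if (x$confounded) "CONFOUNDED - some genes track cortical involvement"
      else "no gene significantly associated with cortical involvement",
      min(x$table$padj, na.rm = TRUE)))
  }
  invisible(x)
}
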