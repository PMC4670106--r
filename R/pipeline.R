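#' Pipeline configuration
#'
#' Collects the analysis constants and input paths for [run_pipeline()].
#' The defaults are the method's canonical settings: 25-gene subset step,
#' top 15 genesets per collection, 5 clustergram groups, FDR < 0.05 DE
#' call, p < 0.05 display mask, 100-gene sliding window, Tukey fence
#' k = 3 and an adjusted-p floor of 1e-300 for the DES.
#'
#' @param counts path to the counts TSV (required by [run_pipeline()]).
#' @param meta path to the sample metadata TSV.
#' @param gmt character vector of GMT paths (may be empty).
#' @param biotypes optional path to a gene -> biotype TSV.
#' @param external_de optional path to an externally produced DE table
#'   TSV (columns `gene_id`, `overall_mean`, `case_mean`, `control_mean`,
#'   `lfc`, `p`, `padj`); bypasses the NB-Wald stage.
#' @param step,top_k,n_groups,de_alpha,mask_alpha,window,trim_k,padj_floor
#'   analysis constants (see Description).
#' @param seed integer seed applied at pipeline start.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts = NULL, meta = NULL, gmt = character(0),
                            biotypes = NULL, external_de = NULL,
                            step = 25, top_k = 15, n_groups = 5,
                            de_alpha = 0.05, mask_alpha = 0.05, window = 100,
                            trim_k = 3, padj_floor = 1e-300, seed = 1L) {
  cfg <- list(counts = counts, meta = meta, gmt = gmt, biotypes = biotypes,
              external_de = external_de, step = as.integer(step),
              top_k = as.integer(top_k), n_groups = as.integer(n_groups),
              de_alpha = de_alpha, mask_alpha = mask_alpha,
              window = as.integer(window), trim_k = trim_k,
              padj_floor = padj_floor, seed = as.integer(seed))
  for (f in c("de_alpha", "mask_alpha"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("configuration error: ", f, " must lie in (0, 1)")
  for (f in c("step", "top_k", "n_groups", "window", "seed"))
    if (cfg[[f]] < 1) stop("configuration error: ", f, " must be positive")
  if (cfg$trim_k <= 0) stop("configuration error: trim_k must be positive")
  if (cfg$padj_floor <= 0 || cfg$padj_floor >= 1)
    stop("configuration error: padj_floor must lie in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> differential expression (or an external DE
#' table) -> DES scoring and descriptive profiles -> ranked-subset
#' enrichment sweep with integrated clustering -> clinical-covariate
#' association, writing every stage's table plus a deterministic
#' `manifest.json` (configuration, its MD5 hash, seed, per-stage row
#' counts) to `outdir`. Identical configuration and inputs produce a
#' byte-identical manifest.
#'
#' @param config a [pipeline_config()] (input paths required).
#' @param outdir output directory, created if needed.
#' @return (invisibly) list with the in-memory stage results and
#'   `manifest` path.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  # validate inputs up front: fail before any compute
  for (f in c("counts", "meta")) {
    if (is.null(config[[f]]))
      stop("configuration error: config$", f, " is required")
    if (!file.exists(config[[f]]))
      stop("configuration error: ", f, " file not found: ", config[[f]])
  }
  for (g in config$gmt)
    if (!file.exists(g)) stop("configuration error: GMT file not found: ", g)
  for (f in c("biotypes", "external_de"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("configuration error: ", f, " file not found: ", config[[f]])
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  counts <- .stage("read_counts", read_counts(config$counts))
  meta <- .stage("read_meta", read_sample_table(config$meta))
  meta <- .align_samples(meta, colnames(counts))
  collections <- .stage("read_gmt", lapply(config$gmt, read_gmt))

  prep <- .stage("preprocess",
                 preprocess_counts(counts, meta$condition, k = config$trim_k))
  write_counts(prep$counts, file.path(outdir, "counts_preprocessed.tsv"))
  write_tsv(data.frame(sample_id = names(prep$size_factors),
                       size_factor = unname(prep$size_factors)),
            file.path(outdir, "size_factors.tsv"))

  de <- if (!is.null(config$external_de)) {
    .stage("external_de", {
      tb <- read_tsv(config$external_de)
      need <- c("gene_id", "overall_mean", "lfc", "p", "padj")
      if (!all(need %in% names(tb)))
        stop("schema error: external DE table needs columns: ",
             paste(need, collapse = ", "))
      tb$is_de <- !is.na(tb$padj) & tb$padj < config$de_alpha
      class(tb) <- c("de_table", "data.frame")
      tb
    })
  } else {
    .stage("dge", nb_wald_test(prep$counts, meta, sf = prep$size_factors,
                               dispersion = prep$dispersion,
                               de_alpha = config$de_alpha))
  }

  scored <- .stage("descore", rank_by_des(de, padj_floor = config$padj_floor))
  write_tsv(scored, file.path(outdir, "de_table_scored.tsv"))
  de_genes <- call_de(de, config$de_alpha)
  ud <- if (length(de_genes) >= config$window) {
    lfc_ranked <- de$lfc[match(de_genes, de$gene_id)]
    updown_profile(lfc_ranked, window = config$window)
  } else NULL
  if (!is.null(ud)) write_tsv(ud, file.path(outdir, "updown_profile.tsv"))
  if (!is.null(config$biotypes)) {
    bt <- biotype_composition(de_genes, read_biotypes(config$biotypes))
    write_tsv(data.frame(biotype = names(bt), proportion = unname(bt)),
              file.path(outdir, "biotype_composition.tsv"))
  }

  profiles <- list(); cgram <- NULL
  if (length(collections) > 0 && length(de_genes) >= config$step) {
    universe <- rownames(prep$counts)
    subsets <- nested_subsets(de_genes, step = config$step)
    profiles <- .stage("enrichsweep", lapply(collections, function(col) {
      pr <- enrichment_profile(col, subsets, universe,
                               mask_alpha = config$mask_alpha)
      tb <- data.frame(set_name = rownames(pr$neglogp), pr$neglogp,
                       check.names = FALSE)
      write_tsv(tb, file.path(outdir, paste0("profile_", col$name, ".tsv")))
      write_tsv(data.frame(set_name = rownames(pr$mask), pr$mask * 1L,
                           check.names = FALSE),
                file.path(outdir, paste0("mask_", col$name, ".tsv")))
      pr
    }))
    if (sum(vapply(profiles, function(p) sum(p$best_p < config$mask_alpha),
                   numeric(1))) >= 2) {
      cgram <- .stage("cluster",
                      suppressWarnings(
                        integrate_and_cluster(profiles, top_k = config$top_k,
                                              n_groups = config$n_groups)))
      write_tsv(data.frame(set_name = rownames(cgram$matrix),
                           group = LETTERS[cgram$groups],
                           dendro_order = order(cgram$row_order),
                           cgram$matrix, check.names = FALSE),
                file.path(outdir, "clustergram.tsv"))
      write_tsv(data.frame(merge1 = cgram$hclust$merge[, 1],
                           merge2 = cgram$hclust$merge[, 2],
                           height = cgram$hclust$height),
                file.path(outdir, "linkage.tsv"))
    }
  }

  assoc <- list()
  case_ix <- which(meta$condition == "HD")
  if (length(case_ix) > 4 && all(c("rin") %in% names(meta))) {
    vst_cases <- prep$vst[, case_ix, drop = FALSE]
    rin <- meta$rin[case_ix]
    covs <- list()
    if ("cag" %in% names(meta) && !anyNA(meta$cag[case_ix]))
      covs$cag <- meta$cag[case_ix]
    if (all(c("cag", "onset") %in% names(meta)) &&
        !anyNA(meta$onset[case_ix]) && !anyNA(meta$cag[case_ix]))
      covs$onset_resid <- residual_onset(meta$onset[case_ix], meta$cag[case_ix])
    for (hv in c("hv_striatal", "hv_cortical"))
      if (hv %in% names(meta) && !anyNA(meta[[hv]][case_ix]))
        covs[[hv]] <- meta[[hv]][case_ix]
    assoc <- .stage("covassoc", lapply(covs, function(cv)
      covariate_regression(vst_cases, cv, rin)))
    for (nm in names(assoc))
      write_tsv(assoc[[nm]], file.path(outdir, paste0("assoc_", nm, ".tsv")))
    if ("hv_cortical" %in% names(covs) && length(de_genes) > 0) {
      chk <- .stage("confound_check",
                    confound_check(prep$counts[, case_ix, drop = FALSE],
                                   de_genes, covs$hv_cortical, rin,
                                   sf = prep$size_factors[case_ix]))
      write_tsv(chk$table, file.path(outdir, "confound_check.tsv"))
      assoc$confound <- chk
    }
  }

  manifest <- .write_manifest(config, outdir, list(
    genes_in = nrow(counts), genes_filtered = length(prep$removed),
    genes_tested = nrow(de), genes_de = length(de_genes),
    collections = length(collections),
    clustered_sets = if (is.null(cgram)) 0L else nrow(cgram$matrix),
    assoc_covariates = length(setdiff(names(assoc), "confound"))))
  invisible(list(preprocess = prep, de = de, scored = scored,
                 de_genes = de_genes, profiles = profiles,
                 clustergram = cgram, assoc = assoc, manifest = manifest))
}

.write_manifest <- function(config, outdir, stage_counts) {
  cfg <- unclass(config)
  cfg <- cfg[order(names(cfg))]
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                               digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  manifest <- list(package = "desweep",
                   version = as.character(utils::packageVersion("desweep")),
                   seed = config$seed, config_hash = hash, config = cfg,
                   stages = stage_counts)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  path
}
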