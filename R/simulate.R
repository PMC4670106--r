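#' Simulation configuration for case/control RNA-seq counts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_counts()]. The defaults emulate the structure of a post-mortem
#' HD prefrontal-cortex cohort: 20 cases vs 49 controls, ~19% of genes
#' differentially expressed with a modest excess of up-regulation (54.8%),
#' a small class of "disease-exclusive" genes whose control-side mean is
#' forced to a near-zero floor, heavy-tailed log-normal baseline expression,
#' and uniform per-sample depth multipliers.
#'
#' @param n_genes number of genes to simulate.
#' @param n_cases,n_controls group sizes.
#' @param de_fraction fraction of genes that are truly differentially
#'   expressed, in `[0, 1]`.
#' @param up_fraction fraction of DE genes that are up-regulated in cases.
#' @param exclusive_fraction fraction of DE genes whose control mean is
#'   forced to `exclusive_floor` (these are always up-regulated).
#' @param lfc_scale mean of the exponential distribution from which DE
#'   log2 fold-change magnitudes are drawn (a floor of 0.25 is added so DE
#'   genes are never null).
#' @param nb_dispersion negative-binomial dispersion alpha, so that
#'   `Var = mu + alpha * mu^2`. Scalar (shared across genes).
#' @param depth_range length-2 positive range of uniform per-sample depth
#'   multipliers.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the
#'   per-gene baseline mean.
#' @param exclusive_floor control-side mean for exclusive genes. Kept
#'   strictly positive so NB sampling stays defined.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cases = 20,
                       n_controls = 49,
                       de_fraction = 0.19,
                       up_fraction = 0.548,
                       exclusive_fraction = 0.02,
                       lfc_scale = 1,
                       nb_dispersion = 0.1,
                       depth_range = c(0.5, 2),
                       base_mean_meanlog = log(100),
                       base_mean_sdlog = 1.5,
                       exclusive_floor = 0.05,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls), de_fraction = de_fraction,
              up_fraction = up_fraction, exclusive_fraction = exclusive_fraction,
              lfc_scale = lfc_scale, nb_dispersion = nb_dispersion,
              depth_range = depth_range, base_mean_meanlog = base_mean_meanlog,
              base_mean_sdlog = base_mean_sdlog,
              exclusive_floor = exclusive_floor, seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_cases < 1L || cfg$n_controls < 1L)
    stop("configuration error: n_genes, n_cases and n_controls must be positive")
  for (f in c("de_fraction", "up_fraction", "exclusive_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " must lie in [0, 1]")
  if (cfg$de_fraction > 0 && cfg$de_fraction * cfg$n_genes < 1)
    stop("configuration error: de_fraction * n_genes must be >= 1 when de_fraction > 0")
  if (cfg$lfc_scale <= 0 || cfg$nb_dispersion <= 0)
    stop("configuration error: lfc_scale and nb_dispersion must be positive")
  if (length(cfg$depth_range) != 2L || any(cfg$depth_range <= 0) ||
      cfg$depth_range[1] > cfg$depth_range[2])
    stop("configuration error: depth_range must be an increasing pair of positive reals")
  if (cfg$exclusive_floor <= 0)
    stop("configuration error: exclusive_floor must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a case/control negative-binomial count matrix with ground truth
#'
#' Counts for gene i in sample j are drawn from
#' `NB(mean = depth_j * base_mean_i * 2^(lfc_i * [case_j]), dispersion = alpha)`.
#' Exclusive genes (a subset of the up-regulated DE genes) have their
#' control-side mean replaced by the configured near-zero floor, emulating
#' genes expressed almost only in disease tissue. The sample table carries
#' condition, age at death (cases younger on average), RIN, and case-only
#' CAG / onset / duration / Vonsattel grade / H-V involvement scores, with
#' onset constructed to correlate negatively with CAG repeat length.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"sim_data"` with elements `counts` (integer
#'   gene x sample matrix), `samples` (data frame of per-sample covariates),
#'   `truth` (data frame: `gene_id`, `base_mean`, `is_de`, `true_lfc`,
#'   `is_exclusive`) and `config`.
#' @details For exclusive genes the realized case/control fold change is
#'   much larger than `true_lfc` because the control mean is floored;
#'   parameter-recovery checks on the fold change should exclude them.
#' @export
simulate_counts <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  n  <- config$n_cases + config$n_controls
  gene_id <- sprintf("gene%05d", seq_len(ng))

  base_mean <- stats::rlnorm(ng, config$base_mean_meanlog, config$base_mean_sdlog)

  n_de  <- round(config$de_fraction * ng)
  de_ix <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer(0)
  is_de <- seq_len(ng) %in% de_ix
  true_lfc <- numeric(ng)
  is_exclusive <- logical(ng)
  if (n_de > 0) {
    up <- stats::runif(n_de) < config$up_fraction
    mag <- 0.25 + stats::rexp(n_de, rate = 1 / config$lfc_scale)
    true_lfc[de_ix] <- ifelse(up, mag, -mag)
    n_excl <- round(config$exclusive_fraction * n_de)
    if (n_excl > n_de)
      stop("configuration error: more exclusive genes requested than DE genes")
    if (n_excl > 0) {
      excl <- sample(de_ix, n_excl)
      true_lfc[excl] <- abs(true_lfc[excl])  # exclusive genes are up-regulated
      is_exclusive[excl] <- TRUE
    }
  }

  samples <- .simulate_samples(config)
  is_case <- samples$condition == "HD"
  depth <- stats::runif(n, config$depth_range[1], config$depth_range[2])
  samples$depth <- depth

  ctrl_mean <- base_mean
  ctrl_mean[is_exclusive] <- config$exclusive_floor
  case_mean <- base_mean * 2^true_lfc

  mu <- outer(ctrl_mean, depth)
  mu[, is_case] <- outer(case_mean, depth[is_case])
  counts <- matrix(stats::rnbinom(ng * n, mu = mu, size = 1 / config$nb_dispersion),
                   nrow = ng, dimnames = list(gene_id, samples$sample_id))
  storage.mode(counts) <- "integer"

  truth <- data.frame(gene_id = gene_id, base_mean = base_mean, is_de = is_de,
                      true_lfc = true_lfc, is_exclusive = is_exclusive,
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples, truth = truth,
                 config = config),
            class = "sim_data")
}

.simulate_samples <- function(config) {
  n_ca <- config$n_cases; n_co <- config$n_controls
  sample_id <- c(sprintf("HD_%03d", seq_len(n_ca)), sprintf("C_%03d", seq_len(n_co)))
  condition <- rep(c("HD", "control"), c(n_ca, n_co))
  # cases die younger and have slightly lower RIN, as in post-mortem HD cohorts
  age <- round(c(pmin(pmax(stats::rnorm(n_ca, 58, 11), 30), 90),
                 pmin(pmax(stats::rnorm(n_co, 69, 16), 36), 106)))
  rin <- round(c(pmin(pmax(stats::rnorm(n_ca, 7.1, 0.9), 5), 10),
                 pmin(pmax(stats::rnorm(n_co, 7.8, 0.7), 5), 10)), 1)
  cag <- onset <- duration <- grade <- hv_str <- hv_cor <- rep(NA_real_, n_ca + n_co)
  ca <- seq_len(n_ca)
  cag[ca] <- pmin(pmax(round(stats::rnorm(n_ca, 45, 3)), 38), 55)
  # longer repeats -> earlier onset (negative correlation by construction)
  onset[ca] <- round(88 - 1.05 * cag[ca] + stats::rnorm(n_ca, 0, 5))
  onset[ca] <- pmin(pmax(onset[ca], 18), age[ca] - 2)
  duration[ca] <- age[ca] - onset[ca]
  grade[ca] <- sample(3:4, n_ca, replace = TRUE, prob = c(0.7, 0.3))
  hv_str[ca] <- round(pmin(pmax(stats::rnorm(n_ca, 2.8, 0.45), 2.0), 4.0), 3)
  hv_cor[ca] <- round(pmin(pmax(stats::rnorm(n_ca, 1.35, 0.5), 0.3), 2.5), 3)
  data.frame(sample_id = sample_id, condition = condition, age_of_death = age,
             rin = rin, cag = cag, onset = onset, duration = duration,
             vonsattel_grade = grade, hv_striatal = hv_str, hv_cortical = hv_cor,
             stringsAsFactors = FALSE)
}

#' @export
print.sim_data <- function(x, ...) {
  cat("Simulated case/control count data\n")
  cat(sprintf("  %d genes x %d samples (%d HD, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$condition == "HD"),
              sum(x$samples$condition == "control")))
  cat(sprintf("  %d DE genes (%d exclusive), seed %d\n",
              sum(x$truth$is_de), sum(x$truth$is_exclusive), x$config$seed))
  invisible(x)
}

#' Simulate geneset collections with optionally planted enrichment
#'
#' Planted sets draw `planted_overlap` members from the top
#' `planted_depth` ranks of `gene_ids` (which must be ordered by planted
#' effect, strongest first) and the remainder uniformly from the rest of the
#' universe, so that a ranked-subset enrichment sweep recovers the planted
#' depth. Non-planted sets are sampled uniformly from the whole universe.
#'
#' @param gene_ids character vector of gene identifiers ranked by planted
#'   effect (the simulation truth ranking).
#' @param n_sets total number of sets, including planted ones.
#' @param set_size integer vector of candidate set sizes; each set's size is
#'   sampled uniformly from it (a scalar gives constant size).
#' @param planted optional data frame with columns `set_name`,
#'   `planted_depth`, `planted_overlap` and optionally `set_size` (per-set
#'   override of the `set_size` argument).
#' @param seed integer RNG seed.
#' @param name collection name.
#' @return A `"geneset_collection"` (see [geneset_collection()]).
#' @export
simulate_genesets <- function(gene_ids, n_sets, set_size = 50,
                              planted = NULL, seed = 1L, name = "sim") {
  stopifnot(is.character(gene_ids), length(gene_ids) > 0, n_sets >= 1)
  set_size <- as.integer(set_size)
  if (any(set_size < 1)) stop("configuration error: set sizes must be positive")
  set.seed(as.integer(seed))
  sets <- list()
  n_planted <- 0L
  if (!is.null(planted)) {
    stopifnot(all(c("set_name", "planted_depth", "planted_overlap") %in% names(planted)))
    n_planted <- nrow(planted)
    if (n_planted > n_sets)
      stop("configuration error: more planted sets than n_sets")
    for (i in seq_len(n_planted)) {
      d <- planted$planted_depth[i]; o <- planted$planted_overlap[i]
      k <- if ("set_size" %in% names(planted)) as.integer(planted$set_size[i])
           else if (length(set_size) == 1L) set_size
           else sample(set_size, 1L)
      if (d > length(gene_ids))
        stop("configuration error: planted_depth exceeds the ranked list length")
      if (o > k)
        stop("configuration error: planted_overlap exceeds the set size")
      if (o > d)
        stop("configuration error: planted_overlap exceeds planted_depth")
      top <- sample(gene_ids[seq_len(d)], o)
      rest <- setdiff(gene_ids, top)
      members <- c(top, if (k > o) sample(rest, k - o))
      sets[[planted$set_name[i]]] <- members
    }
  }
  for (i in seq_len(n_sets - n_planted)) {
    k <- if (length(set_size) == 1L) set_size else sample(set_size, 1L)
    k <- min(k, length(gene_ids))
    sets[[sprintf("random_set_%03d", i)]] <- sample(gene_ids, k)
  }
  geneset_collection(sets, name = name)
}
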