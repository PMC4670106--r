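#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row of sample ids with gene ids in the first column.
#' Lines starting with `#` are treated as schema/comment lines and
#' skipped. Every cell must be a non-negative integer; violations are
#' reported with their gene/sample coordinates. Duplicate gene or sample
#' ids are rejected.
#'
#' @param path TSV file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2) stop("parse error: expected gene id column plus samples")
  gene_id <- df[[1]]
  if (anyDuplicated(gene_id)) stop("schema error: duplicate gene identifiers")
  if (anyDuplicated(colnames(df)[-1])) stop("schema error: duplicate sample identifiers")
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- as.numeric(vals))
  bad <- is.na(num) | num != floor(num) | num < 0
  if (any(bad)) {
    ix <- which(bad)[1]
    r <- (ix - 1) %% nrow(vals) + 1; c_ <- (ix - 1) %/% nrow(vals) + 1
    stop(sprintf("parse error: non-integer count '%s' at gene %s, sample %s",
                 vals[r, c_], gene_id[r], colnames(vals)[c_]))
  }
  out <- matrix(as.integer(num), nrow = nrow(vals),
                dimnames = list(gene_id, colnames(vals)))
  out
}

#' Write a count matrix as TSV
#'
#' @param counts matrix with dimnames.
#' @param path output path.
#' @param id_col name for the gene-id column (default `gene_id`).
#' @export
write_counts <- function(counts, path, id_col = "gene_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write_tsv(df, path)
}

#' Write a data frame as TSV with a schema sidecar comment
#'
#' The first line is `# columns: <name> <name> ...`, declaring the column
#' schema; readers in this package validate against it when present.
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# columns:", paste(colnames(df), collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()], validating the schema comment
#'
#' @param path file path.
#' @param na_strings values read as missing (`unk` markers included).
#' @return data frame.
#' @export
read_tsv <- function(path, na_strings = c("NA", "unk", "")) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  first <- readLines(path, n = 1)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = na_strings, quote = "")
  if (startsWith(first, "# columns:")) {
    declared <- strsplit(sub("^# columns: *", "", first), " ")[[1]]
    if (!identical(declared, colnames(df)))
      stop("schema error: header does not match declared schema in ", path)
  }
  df
}

#' Read a sample metadata table
#'
#' TSV with at least `sample_id` and `condition` columns (values `HD` /
#' `control`); case-only clinical columns (`cag`, `onset`, `duration`,
#' `vonsattel_grade`, `hv_striatal`, `hv_cortical`) may be missing for
#' controls (marker `unk` or `NA`).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df)))
    stop("schema error: sample table needs columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("schema error: duplicate sample ids")
  if (!all(df$condition %in% c("HD", "control")))
    stop("schema error: condition must be 'HD' or 'control'")
  df
}

#' Read a geneset collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Lines with fewer than three
#' fields are a parse error (reported with the line number); lines whose
#' members are all empty are dropped with a warning; duplicate members
#' within a set are deduplicated with a message; duplicate set names are
#' rejected.
#'
#' @param path GMT file path.
#' @param name collection name (default: file name without extension).
#' @return a [geneset_collection()].
#' @export
read_gmt <- function(path, name = NULL) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("parse error: line %d has %d field(s); expected name, description, members",
                   i, length(fields)))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning(sprintf("read_gmt: line %d ('%s') has no members; dropped",
                      i, fields[1]))
      next
    }
    if (anyDuplicated(members)) {
      message(sprintf("read_gmt: duplicate members in set '%s' deduplicated",
                      fields[1]))
      members <- unique(members)
    }
    if (fields[1] %in% names(sets))
      stop("schema error: duplicate set name '", fields[1], "'")
    sets[[fields[1]]] <- members
    descs[fields[1]] <- fields[2]
  }
  col <- geneset_collection(sets, name = name)
  attr(col, "descriptions") <- descs
  col
}

#' Write a geneset collection as GMT
#'
#' @param collection a [geneset_collection()].
#' @param path output path.
#' @param descriptions optional named character vector of set
#'   descriptions (default: the set name).
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "geneset_collection"))
  if (is.null(descriptions)) descriptions <- attr(collection, "descriptions")
  lines <- vapply(names(collection$sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, d, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a child-parent term hierarchy file
#'
#' Two tab-separated columns per line: child set name, parent set name.
#'
#' @param path file path.
#' @return data frame with columns `child` and `parent`.
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("child", "parent"),
                          stringsAsFactors = FALSE, quote = "")
  df
}

#' Read a gene -> biotype map
#'
#' TSV with columns `gene_id` and `biotype`.
#'
#' @param path file path.
#' @return named character vector (gene id -> biotype).
#' @export
read_biotypes <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene_id", "biotype") %in% names(df)))
    stop("schema error: biotype map needs columns gene_id and biotype")
  stats::setNames(as.character(df$biotype), df$gene_id)
}
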