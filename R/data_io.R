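#' Construct a methylation dataset
#'
#' Container for feature-level single-cell methylation counts: `Y[i, j]`
#' methylated CpGs out of `n[i, j]` covered CpGs for cell `i` and feature
#' `j`. Entries that were not observed (no CpG covered) are `NA` in both
#' matrices at exactly the same positions.
#'
#' @param Y cells x features matrix of methylated-CpG counts (may contain NA).
#' @param n cells x features matrix of covered-CpG counts, same NA pattern.
#' @param X optional features x P covariate matrix; first column must be the
#'   intercept (all ones). Defaults to intercept-only.
#' @param cell_ids,feature_ids optional identifiers; default to dimnames or
#'   generated labels.
#' @param group optional per-cell group label (factor or character).
#' @return an object of class `methylation_dataset`.
#' @export
methylation_dataset <- function(Y, n, X = NULL, cell_ids = NULL,
                                feature_ids = NULL, group = NULL) {
  Y <- as.matrix(Y); n <- as.matrix(n)
  if (!all(dim(Y) == dim(n))) stop("Y and n must have identical dimensions")
  cell_ids <- cell_ids %||% rownames(Y) %||% paste0("cell_", seq_len(nrow(Y)))
  feature_ids <- feature_ids %||% colnames(Y) %||%
    paste0("feature_", seq_len(ncol(Y)))
  dimnames(Y) <- dimnames(n) <- list(cell_ids, feature_ids)
  if (is.null(X)) {
    X <- matrix(1, nrow = ncol(Y), ncol = 1,
                dimnames = list(feature_ids, "intercept"))
  } else {
    X <- as.matrix(X)
    if (nrow(X) != ncol(Y)) stop("X must have one row per feature")
    rownames(X) <- feature_ids
  }
  if (!is.null(group)) {
    if (length(group) != nrow(Y)) stop("group must have one entry per cell")
    group <- as.factor(group)
  }
  obj <- structure(list(Y = Y, n = n, X = X, cell_ids = cell_ids,
                        feature_ids = feature_ids, group = group),
                   class = "methylation_dataset")
  validate_dataset(obj)
  obj
}

#' Validate a methylation dataset's invariants
#'
#' Checks the NA patterns of `Y` and `n` match, `0 <= Y <= n`, `n >= 1`
#' where observed, and that the covariate matrix is complete with an
#' intercept first column.
#'
#' @param dataset a [methylation_dataset()].
#' @return the dataset, invisibly; errors describe the first violation.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  Y <- dataset$Y; n <- dataset$n
  if (!identical(is.na(Y), is.na(n)))
    stop("Y and n must be missing at exactly the same entries")
  obs <- !is.na(Y)
  if (any(n[obs] < 1)) stop("observed entries must have n >= 1")
  if (any(Y[obs] < 0) || any(Y[obs] > n[obs]))
    stop("observed entries must satisfy 0 <= Y <= n")
  if (any(Y[obs] != floor(Y[obs])) || any(n[obs] != floor(n[obs])))
    stop("counts must be integer-valued")
  if (anyNA(dataset$X)) stop("covariate matrix X must have no missing values")
  if (!all(dataset$X[, 1] == 1)) stop("first column of X must be all ones")
  if (anyDuplicated(dataset$feature_ids)) stop("feature ids must be unique")
  invisible(dataset)
}

#' @export
print.methylation_dataset <- function(x, ...) {
  obs <- mean(!is.na(x$Y))
  cat(sprintf(
    "methylation_dataset: %d cells x %d features (%.1f%% entries observed)\n",
    nrow(x$Y), ncol(x$Y), 100 * obs))
  if (!is.null(x$group))
    cat("  groups:", paste(levels(x$group), collapse = ", "), "\n")
  cat("  covariates:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Read a long-format methylation count table
#'
#' Reads a TSV/CSV with one row per observed (feature, cell) pair and
#' columns for feature id, cell id, total covered CpGs and methylated CpGs.
#' Pairs absent from the file become missing entries; duplicate pairs are an
#' error.
#'
#' @param path file path (plain or gzip); comma or tab separated, header
#'   required.
#' @param dialect named character vector mapping roles `feature`, `cell`,
#'   `total`, `methylated` to column names in the file.
#' @return a [methylation_dataset()].
#' @export
read_long_table <- function(path,
                            dialect = c(feature = "Feature", cell = "Cell",
                                        total = "total_reads",
                                        methylated = "met_reads")) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- dialect[c("feature", "cell", "total", "methylated")]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  feat <- as.character(df[[need[["feature"]]]])
  cell <- as.character(df[[need[["cell"]]]])
  total <- df[[need[["total"]]]]
  met <- df[[need[["methylated"]]]]
  if (!is.numeric(total) || !is.numeric(met) ||
      any(total != floor(total)) || any(met != floor(met)))
    stop("counts must be integers")
  bad <- which(met > total | met < 0 | total < 1)
  if (length(bad))
    stop("invalid counts (methylated > total, negative, or total < 1) at row ",
         bad[1])
  key <- paste(feat, cell, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (feature, cell) pair at row ", which(duplicated(key))[1])
  cells <- unique(cell); feats <- unique(feat)
  Y <- matrix(NA_real_, length(cells), length(feats),
              dimnames = list(cells, feats))
  n <- Y
  idx <- cbind(match(cell, cells), match(feat, feats))
  Y[idx] <- met
  n[idx] <- total
  methylation_dataset(Y, n)
}

#' Write a long-format methylation count table
#'
#' Inverse of [read_long_table()]: one TSV row per observed (feature, cell)
#' pair with columns `Feature`, `Cell`, `total_reads`, `met_reads`.
#'
#' @param dataset a [methylation_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(dataset, path) {
  validate_dataset(dataset)
  obs <- which(!is.na(dataset$Y), arr.ind = TRUE)
  df <- data.frame(Feature = dataset$feature_ids[obs[, 2]],
                   Cell = dataset$cell_ids[obs[, 1]],
                   total_reads = dataset$n[obs],
                   met_reads = dataset$Y[obs])
  df <- df[order(df$Feature, df$Cell), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell CpG call file
#'
#' Supports the common bisulphite "coverage" dialect (chrom, 1-based
#' position, methylated reads, unmethylated reads) and a "rate" dialect
#' (chrom, position, binary state), where state `s` maps to
#' `(met, unmet) = (s, 1 - s)`. Positions are 1-based.
#'
#' @param path file path (plain or gzip), whitespace- or tab-separated,
#'   no header.
#' @param dialect `"coverage"` or `"rate"`.
#' @param cell_id identifier for the cell; defaults to the file base name.
#' @return an object of class `cpg_call_set`: list with `cell_id` and a
#'   data.frame `records` (chrom, position, met_reads, unmet_reads).
#' @export
read_cpg_calls <- function(path, dialect = c("coverage", "rate"),
                           cell_id = NULL) {
  dialect <- match.arg(dialect)
  cell_id <- cell_id %||% sub("\\.(txt|tsv|cov|gz)+$", "", basename(path))
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (dialect == "coverage") {
    if (ncol(df) < 4) stop("coverage dialect needs 4 columns")
    rec <- data.frame(chrom = as.character(df[[1]]), position = df[[2]],
                      met_reads = df[[3]], unmet_reads = df[[4]],
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(df) < 3) stop("rate dialect needs 3 columns")
    s <- df[[3]]
    if (!all(s %in% c(0, 1))) stop("rate dialect state must be 0 or 1")
    rec <- data.frame(chrom = as.character(df[[1]]), position = df[[2]],
                      met_reads = s, unmet_reads = 1 - s,
                      stringsAsFactors = FALSE)
  }
  if (!is.numeric(rec$position) || any(rec$position != floor(rec$position)) ||
      any(rec$position < 1))
    stop("malformed coordinate: positions must be positive integers (1-based)")
  if (any(rec$met_reads < 0) || any(rec$unmet_reads < 0))
    stop("negative read counts")
  zero <- which(rec$met_reads + rec$unmet_reads < 1)
  if (length(zero))
    stop("uncovered site (0 total reads) at line ", zero[1])
  dup <- duplicated(paste(rec$chrom, rec$position))
  if (any(dup))
    stop("duplicate position within cell at line ", which(dup)[1])
  structure(list(cell_id = cell_id, records = rec), class = "cpg_call_set")
}

#' Build feature annotations
#'
#' Creates the genomic feature set over which CpG calls are aggregated.
#' Exactly one of `windows`, `promoters` or `bed` must be given:
#' * `windows`: list with `chrom_sizes` (named vector), `width`, `step`, and
#'   optional `min_fraction` (default 0.5). Tiles each chromosome with
#'   0-based half-open windows `[k*step, k*step + width)`, clipping the last
#'   window at the chromosome end and discarding clipped windows shorter
#'   than `min_fraction * width`.
#' * `promoters`: list with `tss` (data.frame: chrom, tss 1-based, strand,
#'   gene_id) and `flank` (default 2000). Each promoter is the centered
#'   window of `2 * flank` bp around the TSS (strand-symmetric).
#' * `bed`: path to a BED3+name file (0-based half-open).
#'
#' @param windows,promoters,bed see Details above.
#' @return data.frame of class `feature_annotation` with columns
#'   `feature_id`, `chrom`, `start` (0-based inclusive), `end` (0-based
#'   exclusive), `strand`.
#' @export
make_feature_annotations <- function(windows = NULL, promoters = NULL,
                                     bed = NULL) {
  given <- !c(is.null(windows), is.null(promoters), is.null(bed))
  if (sum(given) != 1)
    stop("give exactly one of windows, promoters, bed")
  if (!is.null(windows)) {
    sizes <- windows$chrom_sizes
    width <- windows$width
    step <- windows$step %||% width
    minf <- windows$min_fraction %||% 0.5
    if (is.null(names(sizes))) stop("chrom_sizes must be named by chromosome")
    if (any(sizes <= 0)) stop("chromosome sizes must be positive")
    if (is.null(width) || width <= 0) stop("window width must be positive")
    out <- do.call(rbind, lapply(names(sizes), function(ch) {
      sz <- sizes[[ch]]
      starts <- seq(0, sz - 1, by = step)
      ends <- pmin(starts + width, sz)
      keep <- (ends - starts) >= minf * width
      if (!any(keep)) return(NULL)
      data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                 strand = "*", stringsAsFactors = FALSE)
    }))
    out$feature_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  } else if (!is.null(promoters)) {
    tss <- promoters$tss
    flank <- promoters$flank %||% 2000
    if (flank <= 0) stop("flank must be positive")
    need <- c("chrom", "tss", "gene_id")
    if (!all(need %in% names(tss)))
      stop("tss table needs columns chrom, tss, gene_id (and optional strand)")
    t0 <- tss$tss  # centered window [t - flank, t + flank)
    out <- data.frame(chrom = as.character(tss$chrom),
                      start = pmax(0, t0 - flank), end = t0 + flank,
                      strand = if ("strand" %in% names(tss))
                        as.character(tss$strand) else "*",
                      feature_id = as.character(tss$gene_id),
                      stringsAsFactors = FALSE)
  } else {
    df <- read.table(bed, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(chrom = as.character(df[[1]]), start = df[[2]],
                      end = df[[3]],
                      strand = if (ncol(df) >= 6) as.character(df[[6]]) else "*",
                      feature_id = if (ncol(df) >= 4) as.character(df[[4]])
                      else sprintf("%s:%d-%d", df[[1]], df[[2]], df[[3]]),
                      stringsAsFactors = FALSE)
  }
  if (any(out$start >= out$end)) stop("annotation with start >= end")
  if (anyDuplicated(out$feature_id)) stop("duplicate feature ids")
  rownames(out) <- NULL
  out <- out[, c("feature_id", "chrom", "start", "end", "strand")]
  class(out) <- c("feature_annotation", "data.frame")
  out
}

#' Aggregate per-CpG calls into feature-level counts
#'
#' For each cell and feature, counts the distinct covered CpG sites inside
#' the feature interval (`n`) and, of those, the sites called methylated
#' (`Y`). Call positions are 1-based; annotations are 0-based half-open, so
#' a site at 1-based position p falls in `[start, end)` iff
#' `start < p <= end`. With `binarize = TRUE` a site is methylated iff
#' `met_reads > unmet_reads`, and tied sites are dropped from both counts.
#' With `binarize = FALSE` every site must already be unambiguous
#' (`met_reads == 0` or `unmet_reads == 0`).
#'
#' @param calls list of `cpg_call_set` objects (one per cell).
#' @param annotations a [make_feature_annotations()] result.
#' @param binarize logical; majority-vote binarization (default `TRUE`).
#' @return a [methylation_dataset()]; cells/features with no covered site
#'   are missing entries.
#' @export
aggregate_to_features <- function(calls, annotations, binarize = TRUE) {
  if (!length(annotations$feature_id)) stop("empty annotation list")
  if (anyDuplicated(annotations$feature_id))
    stop("duplicate feature ids in annotations")
  if (inherits(calls, "cpg_call_set")) calls <- list(calls)
  ann_gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = annotations$start + 1,
                              end = annotations$end))
  feats <- annotations$feature_id
  cells <- vapply(calls, function(cs) cs$cell_id, character(1))
  if (anyDuplicated(cells)) stop("duplicate cell ids among call sets")
  Y <- matrix(NA_real_, length(cells), length(feats),
              dimnames = list(cells, feats))
  n <- Y
  for (ci in seq_along(calls)) {
    rec <- calls[[ci]]$records
    met_state <- rec$met_reads > rec$unmet_reads
    if (binarize) {
      keep <- rec$met_reads != rec$unmet_reads  # ties dropped
    } else {
      amb <- rec$met_reads > 0 & rec$unmet_reads > 0
      if (any(amb))
        stop("ambiguous site (reads on both states) with binarize = FALSE; ",
             "set binarize = TRUE for majority-vote calls")
      keep <- rep(TRUE, nrow(rec))
    }
    if (!any(keep)) next
    site_gr <- GenomicRanges::GRanges(
      seqnames = rec$chrom[keep],
      ranges = IRanges::IRanges(start = rec$position[keep], width = 1))
    hits <- GenomicRanges::findOverlaps(site_gr, ann_gr)
    if (!length(hits)) next
    fidx <- S4Vectors::subjectHits(hits)
    met <- met_state[keep][S4Vectors::queryHits(hits)]
    ncov <- tabulate(fidx, nbins = length(feats))
    nmet <- tabulate(fidx[met], nbins = length(feats))
    covered <- ncov > 0
    n[ci, covered] <- ncov[covered]
    Y[ci, covered] <- nmet[covered]
  }
  methylation_dataset(Y, n)
}
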