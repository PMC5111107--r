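#' Expression matrix container
#'
#' A lightweight container for a log2-scale gene-expression grid (genes in
#' rows, samples in columns) with per-sample dataset-of-origin and platform
#' tags. All downstream operations (probe collapse, centering, merging,
#' classification) accept and return this class.
#'
#' @param values Numeric matrix, genes x samples, with unique rownames
#'   (gene or probe identifiers) and unique colnames (sample identifiers).
#'   Values are assumed to be on log2 scale unless stated otherwise by the
#'   caller (e.g. [delta_ct_transform()] takes a `scale` argument).
#' @param dataset Character; dataset-of-origin tag, either length 1
#'   (recycled) or one per sample.
#' @param platform Character; platform tag, length 1 or one per sample.
#'
#' @return An object of class `crc_matrix`: a list with elements `values`,
#'   `dataset`, `platform`.
#' @export
expression_matrix <- function(values, dataset = "unknown", platform = "unknown") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row and column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated row (gene/probe) identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("non-finite values present; use NA for missing measurements")
  n <- ncol(values)
  if (!length(dataset) %in% c(1L, n))
    stop("`dataset` must have length 1 or one entry per sample")
  if (!length(platform) %in% c(1L, n))
    stop("`platform` must have length 1 or one entry per sample")
  structure(
    list(values = values,
         dataset = stats::setNames(rep_len(as.character(dataset), n), colnames(values)),
         platform = stats::setNames(rep_len(as.character(platform), n), colnames(values))),
    class = "crc_matrix")
}

#' @export
print.crc_matrix <- function(x, ...) {
  cat(sprintf("crc_matrix: %d genes x %d samples (%d dataset(s))\n",
              nrow(x$values), ncol(x$values), length(unique(x$dataset))))
  invisible(x)
}

#' @export
dim.crc_matrix <- function(x) dim(x$values)

# subset samples, keeping tags aligned
subset_samples <- function(em, samples) {
  expression_matrix(em$values[, samples, drop = FALSE],
                    em$dataset[samples], em$platform[samples])
}

#' Read an expression matrix from delimited text
#'
#' Supports a plain TSV layout (first column = gene/probe ids, header row of
#' sample ids) and the GEO series-matrix dialect, where the numeric body is
#' delimited by the `!series_matrix_table_begin` / `!series_matrix_table_end`
#' sentinels and fields may be double-quoted.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"series_matrix"`.
#' @param dataset,platform Tags recorded on the returned matrix.
#' @return A [expression_matrix()] object. Values are taken as log2 scale.
#' @export
load_matrix <- function(path, format = c("tsv", "series_matrix"),
                        dataset = basename(path), platform = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
      stop("series-matrix sentinels not found or empty table in ", path)
    lines <- lines[(begin + 1L):(end - 1L)]
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L)
    stop("malformed header (line 1): expected tab-separated sample ids in ", path)
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample column name(s) in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- fields[-1L]
  nf <- lengths(body)
  bad <- which(nf != length(header))
  if (length(bad))
    stop(sprintf("line %d has %d fields, header has %d", bad[1L] + 1L,
                 nf[bad[1L]], length(header)))
  ids <- vapply(body, `[[`, "", 1L)
  raw <- t(vapply(body, function(f) f[-1L], character(length(sample_ids))))
  raw[raw %in% c("", "NA", "null")] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  conv_fail <- is.na(vals) & !is.na(raw)
  if (any(conv_fail)) {
    idx <- which(conv_fail, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d (id '%s'), sample column '%s': '%s'",
                 idx[1L], ids[idx[1L]], sample_ids[idx[2L]], raw[idx[1L], idx[2L]]))
  }
  dimnames(vals) <- list(ids, sample_ids)
  expression_matrix(vals, dataset = dataset, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' @param em A `crc_matrix`.
#' @param path Output path; first column is named `id`.
#' @export
write_matrix_tsv <- function(em, path) {
  df <- data.frame(id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to one row per gene
#'
#' Implements the probe-selection policy used when merging array platforms:
#' each probe is annotated with its gene; where a preferred ("best") probe is
#' designated for a gene (JetSet-style annotation) and present, that probe's
#' row is used; otherwise, among a gene's mapped probes, the probe with the
#' highest mean expression wins. Probes absent from the map are dropped (the
#' count is reported via a message and an attribute). A row whose identifier
#' already equals a gene symbol in the map is treated as that gene's own
#' measurement, which makes the operation idempotent.
#'
#' @param em A `crc_matrix` with probe-level rows.
#' @param probe_map Data frame with columns `probe`, `gene` and optionally
#'   logical `preferred` (defaults to `FALSE`).
#' @param fallback Resolution for multi-probe genes without a preferred
#'   probe; only `"max_mean"` is implemented.
#' @return A `crc_matrix` with one row per gene; attribute
#'   `dropped_probes` holds the identifiers of unmapped probes.
#' @export
collapse_probes <- function(em, probe_map, fallback = "max_mean") {
  fallback <- match.arg(fallback)
  stopifnot(is.data.frame(probe_map), all(c("probe", "gene") %in% names(probe_map)))
  if (is.null(probe_map$preferred)) probe_map$preferred <- FALSE
  probe_map$probe <- as.character(probe_map$probe)
  probe_map$gene <- as.character(probe_map$gene)

  ids <- rownames(em$values)
  # self-mapping: a row named like a gene is that gene's measurement
  selfrows <- setdiff(intersect(ids, unique(probe_map$gene)), probe_map$probe)
  if (length(selfrows))
    probe_map <- rbind(probe_map,
                       data.frame(probe = selfrows, gene = selfrows,
                                  preferred = FALSE))
  probe_map <- probe_map[probe_map$probe %in% ids, , drop = FALSE]
  if (nrow(probe_map) == 0L)
    stop("no overlap between matrix row identifiers and the probe map")
  dropped <- setdiff(ids, probe_map$probe)
  if (length(dropped))
    message(length(dropped), " unmapped probe(s) dropped")

  pick <- vapply(split(probe_map, probe_map$gene), function(g) {
    if (any(g$preferred)) return(g$probe[g$preferred][1L])
    if (nrow(g) == 1L) return(g$probe)
    mu <- rowMeans(em$values[g$probe, , drop = FALSE], na.rm = TRUE)
    g$probe[which.max(mu)]
  }, "")
  vals <- em$values[pick, , drop = FALSE]
  rownames(vals) <- names(pick)
  out <- expression_matrix(vals, em$dataset, em$platform)
  attr(out, "dropped_probes") <- dropped
  out
}

#' Median-center expression values per gene
#'
#' @param em A `crc_matrix`.
#' @param mode `"gene_median"` subtracts each gene's median (computed over
#'   non-missing values); `"none"` returns the input unchanged.
#' @param scope `"pooled"` uses one median per gene across all samples;
#'   `"per_dataset"` centers within each dataset-of-origin separately.
#' @return A `crc_matrix` whose rows have median 0 within scope (all-missing
#'   genes are left missing, with a warning).
#' @export
center_values <- function(em, mode = c("gene_median", "none"),
                          scope = c("pooled", "per_dataset")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (mode == "none") return(em)
  vals <- em$values
  groups <- if (scope == "pooled") list(all = colnames(vals)) else
    split(colnames(vals), em$dataset)
  for (cols in groups) {
    med <- apply(vals[, cols, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    vals[, cols] <- vals[, cols, drop = FALSE] - med
  }
  if (anyNA(vals) && any(allna <- rowSums(!is.na(vals)) == 0L))
    warning(sum(allna), " gene(s) with no non-missing values left uncentered")
  expression_matrix(vals, em$dataset, em$platform)
}

#' Merge expression matrices and remove redundant samples
#'
#' Pools a list of matrices over their shared genes and removes duplicate
#' samples. Two samples are duplicates when they share an identifier, or when
#' their pairwise Pearson correlation over the shared genes reaches
#' `cor_threshold` (default 0.99; missing values excluded pairwise). Within a
#' duplicate group the first-encountered sample is retained.
#'
#' @param matrices List of `crc_matrix` objects.
#' @param cor_threshold Pearson correlation at or above which two samples are
#'   deemed redundant.
#' @return List with elements `matrix` (pooled `crc_matrix`) and
#'   `duplicates` (data frame: `removed_id`, `kept_id`, `correlation`,
#'   `reason`).
#' @export
merge_and_dedup <- function(matrices, cor_threshold = 0.99) {
  stopifnot(length(matrices) >= 1L)
  shared <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(shared) == 0L) stop("no shared genes across input matrices")

  vals <- do.call(cbind, lapply(matrices, function(m) m$values[shared, , drop = FALSE]))
  dataset <- do.call(c, lapply(matrices, function(m) unname(m$dataset)))
  platform <- do.call(c, lapply(matrices, function(m) unname(m$platform)))
  ids <- colnames(vals)

  removed <- character(0); kept_for <- character(0); corr <- numeric(0); reason <- character(0)

  # identical accession ids merge unconditionally (first kept)
  dup_id <- duplicated(ids)
  if (any(dup_id)) {
    removed <- ids[dup_id]
    kept_for <- removed  # same accession
    corr <- rep(NA_real_, sum(dup_id))
    reason <- rep("identical_id", sum(dup_id))
  }
  keep <- !dup_id
  vals2 <- vals[, keep, drop = FALSE]
  dataset2 <- dataset[keep]; platform2 <- platform[keep]

  if (ncol(vals2) > 1L) {
    cm <- suppressWarnings(stats::cor(vals2, use = "pairwise.complete.obs"))
    retained <- logical(ncol(vals2))
    for (j in seq_len(ncol(vals2))) {
      prior <- which(retained)
      hit <- prior[!is.na(cm[prior, j]) & cm[prior, j] >= cor_threshold]
      if (length(hit)) {
        removed <- c(removed, colnames(vals2)[j])
        kept_for <- c(kept_for, colnames(vals2)[hit[1L]])
        corr <- c(corr, cm[hit[1L], j])
        reason <- c(reason, "expression_correlation")
      } else retained[j] <- TRUE
    }
    vals2 <- vals2[, retained, drop = FALSE]
    dataset2 <- dataset2[retained]; platform2 <- platform2[retained]
  }

  list(matrix = expression_matrix(vals2, dataset2, platform2),
       duplicates = data.frame(removed_id = removed, kept_id = kept_for,
                               correlation = corr, reason = reason,
                               stringsAsFactors = FALSE))
}

#' Read a clinical annotation table
#'
#' Expects a TSV with at least `sample_id`, `rfs_time` (months) and
#' `rfs_event` (0/1); the optional columns `stage` (I--IV), `msi`
#' (MSI/MSS), `gender`, `age`, `grade`, `location`, `t`, `n`, `m` are carried
#' through when present.
#'
#' @param path TSV path.
#' @return Validated data frame (see [validate_clinical()]).
#' @export
load_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_clinical(df)
}

#' Validate a clinical table against its invariants
#'
#' @param df Data frame with `sample_id`, `rfs_time`, `rfs_event`.
#' @param em Optional companion `crc_matrix`; when given, every sample must
#'   be present in the matrix.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_clinical <- function(df, em = NULL) {
  req <- c("sample_id", "rfs_time", "rfs_event")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table")
  if (any(df$rfs_time < 0, na.rm = TRUE)) stop("negative rfs_time")
  ev <- df$rfs_event[!is.na(df$rfs_event)]
  if (!all(ev %in% c(0, 1))) stop("rfs_event must be 0/1")
  if (!is.null(df$stage)) {
    bad <- setdiff(unique(df$stage[!is.na(df$stage)]), c("I", "II", "III", "IV"))
    if (length(bad)) stop("invalid stage value(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(em)) {
    absent <- setdiff(df$sample_id, colnames(em$values))
    if (length(absent))
      stop("clinical sample(s) absent from expression matrix: ",
           paste(utils::head(absent, 5L), collapse = ", "))
  }
  df
}
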