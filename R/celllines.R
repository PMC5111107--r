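#' Consensus subtype call from replicate cell-line arrays
#'
#' A cell line measured on several arrays gets a final label only when at
#' least 60\% of its arrays agree (inclusive: a 2-of-3 split at 66.7\%
#' passes, a 1-of-2 split at 50\% does not); otherwise the call is NA.
#' Arrays whose own call is NA count toward the denominator but cannot
#' carry the consensus.
#'
#' @param per_array_labels Character vector of per-array labels (NA
#'   allowed); must be non-empty.
#' @param min_agreement Consensus fraction (default 0.6).
#' @return The consensus label, or NA.
#' @export
tally_assign <- function(per_array_labels, min_agreement = 0.6) {
  if (length(per_array_labels) == 0L) stop("no arrays supplied")
  tab <- table(per_array_labels[!is.na(per_array_labels)])
  if (length(tab) == 0L) return(NA_character_)
  top <- which(tab == max(tab))
  if (length(top) > 1L) return(NA_character_)
  if (max(tab) / length(per_array_labels) >= min_agreement)
    names(tab)[top] else NA_character_
}

#' Classify a cell-line panel and form consensus calls
#'
#' Runs each signature on the cell-line array matrix (cohort-relative
#' references — medians, percentiles — are computed within the panel, which
#' is classified as a standalone set) and collapses replicate arrays per
#' line with [tally_assign()].
#'
#' @param em A `crc_matrix` of cell-line arrays.
#' @param line_of_array Character vector mapping each array (matrix column)
#'   to its cell line; names are array ids.
#' @param signatures Named list of `crc_signature` objects.
#' @param models Named list of trained models for `trained_model` rules.
#' @return List: `assignments` (data frame `cell_line`, `classifier`,
#'   `label`, `n_arrays`), `array_calls` (per-array long calls).
#' @export
classify_cellline_panel <- function(em, line_of_array, signatures,
                                    models = list()) {
  if (is.null(names(line_of_array)))
    names(line_of_array) <- colnames(em$values)
  line_of_array <- line_of_array[colnames(em$values)]
  calls <- classify_cohort(em, signatures, models)
  calls$cell_line <- line_of_array[calls$sample_id]
  rows <- list()
  for (cl in unique(calls$classifier)) {
    sub <- calls[calls$classifier == cl, , drop = FALSE]
    for (ln in unique(sub$cell_line)) {
      labs <- sub$label[sub$cell_line == ln]
      rows[[length(rows) + 1L]] <-
        data.frame(cell_line = ln, classifier = cl,
                   label = tally_assign(labs), n_arrays = length(labs),
                   stringsAsFactors = FALSE)
    }
  }
  list(assignments = do.call(rbind, rows), array_calls = calls)
}

#' Join mutation annotations onto cell-line assignments
#'
#' @param assignments Data frame with a `cell_line` column.
#' @param mutation_table Long data frame (or TSV path) with columns
#'   `cell_line`, `gene`, `status` (`M`, `WT` or NA). Conflicting duplicate
#'   rows for one line/gene raise an error; lines absent from the table get
#'   NA for every gene (with a warning).
#' @param genes Mutation genes reported as columns (default the six
#'   benchmark genes).
#' @return `assignments` with one added column per mutation gene.
#' @export
annotate_mutations <- function(assignments, mutation_table,
                               genes = c("KRAS", "BRAF", "PIK3CA", "PTEN",
                                         "TP53", "APC")) {
  if (is.character(mutation_table))
    mutation_table <- utils::read.delim(mutation_table, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_line", "gene", "status") %in% names(mutation_table)))
  bad <- setdiff(unique(mutation_table$status[!is.na(mutation_table$status)]),
                 c("M", "WT"))
  if (length(bad)) stop("invalid mutation status value(s): ",
                        paste(bad, collapse = ", "))
  key <- paste(mutation_table$cell_line, mutation_table$gene)
  dup <- duplicated(key)
  if (any(dup)) {
    first <- mutation_table$status[match(key[dup], key)]
    if (any(!is.na(first) & !is.na(mutation_table$status[dup]) &
            first != mutation_table$status[dup]))
      stop("conflicting duplicate mutation rows for: ",
           paste(unique(key[dup]), collapse = ", "))
    mutation_table <- mutation_table[!dup, , drop = FALSE]
  }
  absent <- setdiff(unique(assignments$cell_line), mutation_table$cell_line)
  if (length(absent))
    warning(length(absent), " cell line(s) absent from mutation table: ",
            paste(absent, collapse = ", "))
  for (g in genes) {
    sub <- mutation_table[mutation_table$gene == g, , drop = FALSE]
    assignments[[g]] <- sub$status[match(assignments$cell_line, sub$cell_line)]
  }
  assignments
}

#' Patient subtype prevalence versus available cell-line models
#'
#' Pairs, per classifier, the patient label proportions (with NA calls as
#' their own category) with the number of consensus-assigned cell lines per
#' label, and flags labels for which no cell-line model exists.
#'
#' @param patient_calls Long subtype-call data frame for patients.
#' @param cellline_assignments Consensus assignment data frame
#'   (`cell_line`, `classifier`, `label`).
#' @return Data frame `classifier`, `label`, `patient_pct`, `n_models`,
#'   `unmodeled` (TRUE where patients carry a label with zero models).
#' @export
subtype_prevalence_vs_models <- function(patient_calls, cellline_assignments) {
  rows <- list()
  for (cl in intersect(unique(patient_calls$classifier),
                       unique(cellline_assignments$classifier))) {
    p <- patient_calls$label[patient_calls$classifier == cl]
    p[is.na(p)] <- "NA"
    m <- cellline_assignments$label[cellline_assignments$classifier == cl]
    m <- m[!is.na(m)]
    labs <- union(unique(p), unique(m))
    pt <- table(factor(p, levels = labs))
    mt <- table(factor(m, levels = labs))
    rows[[length(rows) + 1L]] <-
      data.frame(classifier = cl, label = labs,
                 patient_pct = 100 * as.vector(pt) / length(p),
                 n_models = as.vector(mt),
                 unmodeled = as.vector(pt) > 0 & as.vector(mt) == 0 &
                   labs != "NA",
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
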