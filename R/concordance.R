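#' Cramer's V between two categorical labelings
#'
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))` from the r x c contingency
#' table of the two label vectors, with the uncorrected chi-squared
#' statistic. Pairs where either label is NA are removed first; if either
#' vector has a single level after removal the statistic is undefined
#' (NA, with a warning).
#'
#' @param a,b Equal-length label vectors (character/factor; NA allowed).
#' @return Cramer's V in \[0, 1\], or NA.
#' @export
cramers_v <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- as.character(a)[keep]; b <- as.character(b)[keep]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    warning("a label vector has fewer than 2 levels after NA removal; V undefined")
    return(NA_real_)
  }
  tab <- table(a, b)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1L)))
  min(v, 1)
}

#' Pairwise Cramer's V matrix over classifier outputs
#'
#' @param calls Long data frame of subtype calls (`sample_id`,
#'   `classifier`, `label`).
#' @return Symmetric matrix of Cramer's V values (diagonal 1; NA where
#'   undefined).
#' @export
concordance_matrix <- function(calls) {
  wide <- label_table(calls)
  cls <- colnames(wide)
  v <- matrix(NA_real_, length(cls), length(cls), dimnames = list(cls, cls))
  diag(v) <- 1
  if (length(cls) < 2L) return(v)
  for (i in seq_len(length(cls) - 1L)) for (j in (i + 1L):length(cls)) {
    v[i, j] <- v[j, i] <- suppressWarnings(cramers_v(wide[, i], wide[, j]))
  }
  v
}

label_table <- function(calls) {
  samples <- unique(calls$sample_id)
  cls <- unique(calls$classifier)
  wide <- matrix(NA_character_, length(samples), length(cls),
                 dimnames = list(samples, cls))
  wide[cbind(match(calls$sample_id, samples), match(calls$classifier, cls))] <-
    calls$label
  wide
}

#' Concordance of one prognosis label between two classifiers
#'
#' Builds, per classifier, the indicator "sample carries the named label",
#' and measures the association of the two indicators with Cramer's V over
#' the samples classified by both. Because agreement on a prognosis group
#' is directional, a negative association (observed co-occurrence below
#' the independence expectation) reports 0; a degenerate indicator (all
#' positive or all negative) gives NA.
#'
#' @param calls_a,calls_b Subtype call data frames of the two classifiers.
#' @param label_a,label_b The label of interest in each classifier
#'   (e.g. each classifier's bad-prognosis label).
#' @return Sign-clamped Cramer's V in \[0, 1\], or NA.
#' @export
prognosis_label_concordance <- function(calls_a, calls_b, label_a, label_b) {
  if (!label_a %in% calls_a$label || !label_b %in% calls_b$label) {
    warning("requested label absent from calls")
    return(NA_real_)
  }
  common <- intersect(calls_a$sample_id[!is.na(calls_a$label)],
                      calls_b$sample_id[!is.na(calls_b$label)])
  ia <- calls_a$label[match(common, calls_a$sample_id)] == label_a
  ib <- calls_b$label[match(common, calls_b$sample_id)] == label_b
  v <- suppressWarnings(cramers_v(ia, ib))
  if (is.na(v)) return(NA_real_)
  expected <- sum(ia) * sum(ib) / length(ia)
  if (sum(ia & ib) < expected) 0 else v
}

#' Gene-list overlap percentages between signatures
#'
#' `entry(i, j) = 100 * |genes_i intersect genes_j| / |genes_i|`:
#' row-normalized and therefore asymmetric (a small signature fully
#' contained in a large one scores 100 one way and the size ratio the
#' other).
#'
#' @param signatures List of `crc_signature` objects (>= 2).
#' @return Numeric percentage matrix, rows/columns named by classifier.
#' @export
signature_overlap_matrix <- function(signatures) {
  stopifnot(length(signatures) >= 2L)
  gl <- lapply(signatures, function(s) unique(s$genes$symbol))
  nm <- vapply(signatures, function(s) s$name, "")
  out <- matrix(0, length(gl), length(gl), dimnames = list(nm, nm))
  for (i in seq_along(gl)) for (j in seq_along(gl))
    out[i, j] <- 100 * length(intersect(gl[[i]], gl[[j]])) / length(gl[[i]])
  out
}

#' Gene-score ranking across signatures
#'
#' Each gene's score is
#' `[number of signatures containing the gene] * [sum over those signatures
#' of 1 / signature size]`; genes are ranked by descending score with
#' alphabetical tie order.
#'
#' @param signatures List of `crc_signature` objects.
#' @return Data frame `gene`, `n_signatures`, `score`, sorted by rank.
#' @export
gene_score_ranking <- function(signatures) {
  stopifnot(length(signatures) >= 1L)
  gl <- lapply(signatures, function(s) unique(s$genes$symbol))
  sizes <- lengths(gl)
  genes <- sort(unique(unlist(gl)))
  contains <- vapply(gl, function(g) genes %in% g,
                     logical(length(genes)))
  contains <- matrix(contains, nrow = length(genes))
  n_sig <- rowSums(contains)
  prop <- drop(contains %*% (1 / sizes))
  out <- data.frame(gene = genes, n_signatures = n_sig,
                    score = n_sig * prop, stringsAsFactors = FALSE)
  out[order(-out$score, out$gene), , drop = FALSE]
}
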