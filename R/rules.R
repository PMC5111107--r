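#' Delta-Ct transform of an expression matrix
#'
#' Emulates RT-PCR-style relative expression from array data: per sample,
#' every gene value is replaced by
#' `constant - (log2(mean(housekeeping)) - log2(gene))`,
#' i.e. the gene's log2 level relative to the housekeeping panel, offset by
#' a fixed constant (-15 in the recurrence-score setup). With
#' `mean_mode = "arithmetic"` the housekeeping mean is taken on the linear
#' scale (matching `log2(mean(housekeeping))`); `"geometric"` averages the
#' log2 values directly.
#'
#' @param em A `crc_matrix`.
#' @param housekeeping Housekeeping gene symbols; all must be present.
#' @param constant Additive constant (default -15).
#' @param mean_mode `"arithmetic"` or `"geometric"`.
#' @param scale Scale of the input values: `"log2"` (default) or
#'   `"linear"` (log-transformed here; nonpositive values error).
#' @return A `crc_matrix` of transformed values.
#' @export
delta_ct_transform <- function(em, housekeeping, constant = -15,
                               mean_mode = c("arithmetic", "geometric"),
                               scale = c("log2", "linear")) {
  mean_mode <- match.arg(mean_mode)
  scale <- match.arg(scale)
  miss <- setdiff(housekeeping, rownames(em$values))
  if (length(miss))
    stop("housekeeping gene(s) missing from matrix: ", paste(miss, collapse = ", "))
  vals <- em$values
  if (scale == "linear") {
    if (any(vals <= 0, na.rm = TRUE))
      stop("nonpositive linear-scale value(s); cannot log-transform")
    vals <- log2(vals)
  }
  hk <- vals[housekeeping, , drop = FALSE]
  log2_hk_mean <- if (mean_mode == "arithmetic")
    log2(colMeans(2^hk, na.rm = TRUE)) else colMeans(hk, na.rm = TRUE)
  out <- constant - (matrix(log2_hk_mean, nrow(vals), ncol(vals), byrow = TRUE) - vals)
  dimnames(out) <- dimnames(vals)
  expression_matrix(out, em$dataset, em$platform)
}

#' Weighted linear signature score
#'
#' `score = intercept + sum(weight_g * expr_g)` over the signature genes
#' present in the matrix. With uniform weights `1/n` and intercept 0 this
#' reproduces the signature-mean score used by average-expression
#' classifiers.
#'
#' @param em A `crc_matrix`.
#' @param sig A `crc_signature` with a weighted rule.
#' @return Named numeric vector of per-sample scores.
#' @export
score_linear <- function(em, sig) {
  g <- sig$genes[sig$genes$symbol %in% rownames(em$values), , drop = FALSE]
  if (nrow(g) == 0L) stop("no signature genes present in matrix")
  drop(crossprod(em$values[g$symbol, , drop = FALSE], g$weight)) +
    (sig$rule$intercept %||% 0)
}

score_signature_mean <- function(em, sig) {
  g <- intersect(sig$genes$symbol, rownames(em$values))
  if (length(g) == 0L) stop("no signature genes present in matrix")
  colMeans(em$values[g, , drop = FALSE], na.rm = TRUE)
}

#' Product-ratio signature score
#'
#' Evaluates scores of the form `sum_k sign_k * abs(prod(num_k) / den_k)`
#' (the five-gene recurrence formula is
#' `abs(BMI1*VEGFA/H3F3B) - abs(ETV6*H3F3B/RPS10)`). When the rule sets
#' `housekeeping_adjust`, the mean expression of the signature's
#' housekeeping panel is subtracted from every signature gene per sample
#' before the formula is applied. A zero denominator leaves that sample's
#' score undefined (NA, with a warning).
#'
#' @inheritParams score_linear
#' @return Named numeric vector of per-sample scores (NA where undefined).
#' @export
score_product_ratio <- function(em, sig) {
  r <- sig$rule
  need <- unique(unlist(lapply(r$terms, function(t) c(t$num, t$den))))
  miss <- setdiff(need, rownames(em$values))
  if (length(miss))
    stop("signature gene(s) missing from matrix: ", paste(miss, collapse = ", "))
  vals <- em$values[need, , drop = FALSE]
  if (isTRUE(r$housekeeping_adjust)) {
    hk_miss <- setdiff(sig$housekeeping, rownames(em$values))
    if (length(hk_miss))
      stop("housekeeping gene(s) missing: ", paste(hk_miss, collapse = ", "))
    hk_mean <- colMeans(em$values[sig$housekeeping, , drop = FALSE], na.rm = TRUE)
    vals <- sweep(vals, 2L, hk_mean, "-")
  }
  scores <- rep(0, ncol(vals))
  undef <- rep(FALSE, ncol(vals))
  for (t in r$terms) {
    den <- vals[t$den, ]
    undef <- undef | (!is.na(den) & den == 0)
    num <- apply(vals[t$num, , drop = FALSE], 2L, prod)
    scores <- scores + t$sign * abs(num / den)
  }
  scores[undef] <- NA_real_
  if (any(undef))
    warning(sum(undef), " sample(s) with zero denominator left unclassified")
  stats::setNames(scores, colnames(vals))
}

#' Label scores by fixed or cohort-relative cutoffs
#'
#' Fixed mode assigns labels by interval: strictly below the first cutoff is
#' the first label, strictly above the last cutoff the last label, and
#' boundary values fall in the enclosed interval (a recurrence score of
#' exactly 30 or 40 is intermediate; with a single cutoff, a score exactly
#' at the cutoff goes to the lower group). `cohort_median` splits at the
#' cohort median with ties to the lower group; `tertile` assigns three
#' equal-quantile groups.
#'
#' @param scores Named per-sample scores (NA allowed; NA scores yield NA
#'   labels).
#' @param rule A `crc_rule` carrying `cutoff_mode` and `cutoffs`.
#' @param labels Character vector of output labels, lowest group first.
#' @return Character vector of labels aligned with `scores` (NA where
#'   unclassifiable).
#' @export
classify_by_cutoff <- function(scores, rule, labels) {
  mode <- rule$cutoff_mode %||% "cohort_median"
  lab <- rep(NA_character_, length(scores))
  ok <- !is.na(scores)
  if (mode == "fixed") {
    cuts <- sort(rule$cutoffs)
    k <- length(cuts)
    stopifnot(length(labels) == k + 1L)
    idx <- findInterval(scores[ok], cuts) + 1L
    idx[scores[ok] <= cuts[k]] <- pmin(idx[scores[ok] <= cuts[k]], k)
    lab[ok] <- labels[idx]
  } else if (mode == "cohort_median") {
    stopifnot(length(labels) == 2L)
    if (length(unique(scores[ok])) < 2L) {
      warning("fewer than 2 distinct scores; cohort-relative split undefined")
      return(stats::setNames(lab, names(scores)))
    }
    med <- stats::median(scores[ok])
    lab[ok] <- ifelse(scores[ok] > med, labels[2L], labels[1L])
  } else if (mode == "tertile") {
    stopifnot(length(labels) == 3L)
    if (length(unique(scores[ok])) < 2L) {
      warning("fewer than 2 distinct scores; cohort-relative split undefined")
      return(stats::setNames(lab, names(scores)))
    }
    cuts <- stats::quantile(scores[ok], c(1, 2) / 3, names = FALSE)
    lab[ok] <- labels[vapply(scores[ok], function(s) sum(s > cuts), 0L) + 1L]
  } else stop("unknown cutoff mode: ", mode)
  stats::setNames(lab, names(scores))
}

# per-gene risk references for tally rules; constant genes never score
tally_positive <- function(em, genes, rule) {
  ref <- rule$reference %||% "median"
  pos <- matrix(FALSE, nrow(genes), ncol(em$values),
                dimnames = list(genes$symbol, colnames(em$values)))
  for (i in seq_len(nrow(genes))) {
    v <- em$values[genes$symbol[i], ]
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning("gene ", genes$symbol[i], " is constant; it never scores positive")
      next
    }
    up <- genes$direction[i] != "down_is_risk"
    cut <- if (ref == "median") stats::median(v, na.rm = TRUE) else
      stats::quantile(v, (if (up) rule$hi %||% 80 else rule$lo %||% 20) / 100,
                      na.rm = TRUE, names = FALSE)
    pos[i, ] <- !is.na(v) & (if (up) v > cut else v < cut)
  }
  pos
}

#' Per-gene tally classification
#'
#' Counts, per sample, the signature genes at risk-associated levels: an
#' `up_is_risk` gene scores positive above its cohort reference (median, or
#' the high percentile), a `down_is_risk` gene below its reference (median
#' or the low percentile). With a rule `threshold`, samples with at least
#' that many positive genes get the second (risk) label; without one, the
#' count itself is the label (the 0/1/2/3 scheme).
#'
#' @inheritParams score_linear
#' @return Data frame of subtype calls (`sample_id`, `classifier`, `label`,
#'   `score` = tally count, `confidence` = NA).
#' @export
classify_by_tally <- function(em, sig) {
  g <- sig$genes[sig$genes$symbol %in% rownames(em$values), , drop = FALSE]
  if (nrow(g) == 0L) stop("no signature genes present in matrix")
  tally <- colSums(tally_positive(em, g, sig$rule))
  lab <- if (is.null(sig$rule$threshold)) as.character(tally) else
    ifelse(tally >= sig$rule$threshold, sig$labels$label[2L], sig$labels$label[1L])
  subtype_calls(colnames(em$values), sig$name, lab, score = tally)
}

#' Two-partition mean comparison
#'
#' Per sample, compares the mean expression of gene group G1 with that of
#' group G2; `mean(G1) < mean(G2)` yields the second label (the
#' mutant-like call in the BRAF surrogate classifier), ties and the reverse
#' yield the first. A partition with no covered genes gives NA.
#'
#' @inheritParams score_linear
#' @return Data frame of subtype calls; `score` is `mean(G2) - mean(G1)`.
#' @export
classify_by_group_means <- function(em, sig) {
  r <- sig$rule
  g1 <- intersect(r$g1, rownames(em$values))
  g2 <- intersect(r$g2, rownames(em$values))
  if (length(g1) == 0L || length(g2) == 0L) {
    warning("a partition has no covered genes; all calls NA")
    return(subtype_calls(colnames(em$values), sig$name, NA_character_))
  }
  m1 <- colMeans(em$values[g1, , drop = FALSE], na.rm = TRUE)
  m2 <- colMeans(em$values[g2, , drop = FALSE], na.rm = TRUE)
  lab <- ifelse(m1 < m2, sig$labels$label[2L], sig$labels$label[1L])
  lab[is.na(m1) | is.na(m2)] <- NA_character_
  subtype_calls(colnames(em$values), sig$name, lab, score = m2 - m1)
}

# canonical SubtypeCall data frame
subtype_calls <- function(sample_id, classifier, label, score = NA_real_,
                          confidence = NA_real_) {
  data.frame(sample_id = sample_id, classifier = classifier,
             label = as.character(label),
             score = as.numeric(score), confidence = as.numeric(confidence),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a cohort with one signature
#'
#' Front door for the declarative classifiers: applies the signature's
#' delta-Ct pre-transform when declared, checks gene coverage against the
#' floor (non-evaluable signatures yield all-NA calls with a warning),
#' computes the rule's score, and assigns labels. Trained-model rules
#' delegate to [predict.crc_model()] and require `model`.
#'
#' @param em A `crc_matrix`.
#' @param sig A `crc_signature`.
#' @param model Optional `crc_model` for `trained_model` rules.
#' @param coverage_floor Minimum fraction of signature genes that must be
#'   measurable (see [validate_signature()]).
#' @return Data frame of subtype calls, one row per sample.
#' @export
classify_samples <- function(em, sig, model = NULL, coverage_floor = 0.8) {
  cov <- validate_signature(sig, em, floor = coverage_floor)
  if (!cov$evaluable) {
    warning("signature '", sig$name, "' non-evaluable: coverage ",
            sprintf("%.3f", cov$coverage), " < ", coverage_floor)
    return(subtype_calls(colnames(em$values), sig$name, NA_character_))
  }
  if (!is.null(sig$delta_ct))
    em <- delta_ct_transform(em, sig$housekeeping,
                             constant = sig$delta_ct$constant %||% -15,
                             mean_mode = sig$delta_ct$mean_mode %||% "arithmetic")
  r <- sig$rule
  switch(r$kind,
    linear_cutoff = {
      s <- score_linear(em, sig)
      subtype_calls(names(s), sig$name, classify_by_cutoff(s, r, sig$labels$label),
                    score = s)
    },
    signature_mean_split = {
      s <- score_signature_mean(em, sig)
      rr <- r; rr$cutoff_mode <- r$cutoff_mode %||% "cohort_median"
      subtype_calls(names(s), sig$name, classify_by_cutoff(s, rr, sig$labels$label),
                    score = s)
    },
    product_ratio = {
      s <- score_product_ratio(em, sig)
      rr <- r; rr$cutoff_mode <- r$cutoff_mode %||% "cohort_median"
      subtype_calls(names(s), sig$name, classify_by_cutoff(s, rr, sig$labels$label),
                    score = s)
    },
    tally = classify_by_tally(em, sig),
    group_mean_compare = classify_by_group_means(em, sig),
    dual_median = {
      ga <- sig$genes[sig$genes$model == "a" & sig$genes$symbol %in% rownames(em$values), ]
      gb <- sig$genes[sig$genes$model == "b" & sig$genes$symbol %in% rownames(em$values), ]
      if (nrow(ga) == 0L || nrow(gb) == 0L) stop("a dual_median sub-model has no covered genes")
      sa <- drop(crossprod(em$values[ga$symbol, , drop = FALSE], ga$weight))
      sb <- drop(crossprod(em$values[gb$symbol, , drop = FALSE], gb$weight))
      hi <- sa > stats::median(sa, na.rm = TRUE) & sb > stats::median(sb, na.rm = TRUE)
      lab <- ifelse(hi, sig$labels$label[2L], sig$labels$label[1L])
      lab[is.na(sa) | is.na(sb)] <- NA_character_
      subtype_calls(colnames(em$values), sig$name, lab, score = sa + sb)
    },
    trained_model = {
      if (is.null(model)) stop("signature '", sig$name,
                               "' uses a trained model; supply `model`")
      calls <- predict(model, em,
                       confidence_floor = r$confidence_floor %||% 0)
      calls$classifier <- sig$name
      calls
    },
    stop("unhandled rule kind: ", r$kind))
}

#' Classify a cohort with many signatures
#'
#' @param em A `crc_matrix`.
#' @param signatures Named list of `crc_signature` objects.
#' @param models Named list of `crc_model` objects for `trained_model`
#'   rules (matched by signature name).
#' @param coverage_floor See [classify_samples()].
#' @return One long data frame of subtype calls.
#' @export
classify_cohort <- function(em, signatures, models = list(), coverage_floor = 0.8) {
  do.call(rbind, lapply(signatures, function(sig)
    classify_samples(em, sig, model = models[[sig$name]],
                     coverage_floor = coverage_floor)))
}
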