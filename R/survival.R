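#' Two-group Cox proportional hazards comparison
#'
#' Fits a proportional-hazards model with a single binary group term (Efron
#' handling of tied event times) and reports the hazard ratio of the second
#' factor level versus the first, its Wald 95\% confidence interval and
#' Wald p-value.
#'
#' @param times Follow-up times (months, >= 0, finite).
#' @param events Event indicators (0/1).
#' @param group Two-level factor (or coercible); the first level is the
#'   reference.
#' @param comparison Name recorded on the result.
#' @return Object of class `crc_survresult`: `comparison`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `coef`, `se`, `n`
#'   (per-group sizes), `events` (per-group event counts), `ties`.
#' @export
cox_two_group <- function(times, events, group, comparison = "group") {
  if (any(!is.finite(times))) stop("non-finite follow-up time(s)")
  if (any(times < 0)) stop("negative follow-up time(s)")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels, got ", nlevels(g))
  ev <- tapply(events, g, sum)
  if (any(ev == 0))
    stop("zero events in group: ", paste(names(ev)[ev == 0], collapse = ", "))
  fit <- survival::coxph(survival::Surv(times, events) ~ g, ties = "efron")
  co <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  structure(list(comparison = comparison,
                 hazard_ratio = exp(co),
                 ci_low = exp(co - stats::qnorm(0.975) * se),
                 ci_high = exp(co + stats::qnorm(0.975) * se),
                 p_value = 2 * stats::pnorm(-abs(co / se)),
                 coef = co, se = se,
                 n = as.vector(table(g)), events = as.vector(ev),
                 groups = levels(g), ties = "efron"),
            class = "crc_survresult")
}

#' @export
print.crc_survresult <- function(x, ...) {
  cat(sprintf("%s: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g [%s vs %s, n = %d/%d]\n",
              x$comparison, x$hazard_ratio, x$ci_low, x$ci_high, x$p_value,
              x$groups[2L], x$groups[1L], x$n[2L], x$n[1L]))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test
#'
#' @inheritParams cox_two_group
#' @param group Grouping factor (2+ levels).
#' @return List: `curves` (data frame `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`), `chisq`, `df`, `p_value` (log-rank).
#' @export
km_logrank <- function(times, events, group) {
  if (any(!is.finite(times))) stop("non-finite follow-up time(s)")
  g <- droplevels(as.factor(group))
  sf <- survival::survfit(survival::Surv(times, events) ~ g)
  strata <- if (is.null(sf$strata)) rep(levels(g)[1L], length(sf$time)) else
    rep(sub("^g=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = strata, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, n_censor = sf$n.censor,
                       surv = sf$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(sd$n) - 1L
  list(curves = curves, chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(unname(sd$chisq), df, lower.tail = FALSE))
}

#' Best-versus-worst cohort hazard ratio for a classifier
#'
#' Reproduces the benchmark's survival comparison: after optional stage
#' filtering and training-set exclusion, the classifier's labels are ranked
#' by their one-vs-rest log hazard; the lowest-hazard (best-outcome) and
#' highest-hazard (worst-outcome) labels are kept, intermediate and
#' unclassified samples are excluded, and a two-group Cox model compares
#' the extremes (worst vs best, so HR > 1 means the classifier separates
#' prognosis in the expected direction). For a 2-label classifier the
#' selection is the identity and the result equals [cox_two_group()] on
#' those labels.
#'
#' @param calls Subtype call data frame for one classifier.
#' @param clinical Clinical table with `sample_id`, `rfs_time`,
#'   `rfs_event`, optionally `stage` and `dataset`.
#' @param stage_filter Optional subset of stages (e.g. `c("II", "III")`).
#' @param exclude_datasets Optional dataset tags removed before the fit
#'   (the classifier's original training cohorts).
#' @return A `crc_survresult`; attribute `label_rank` holds the per-label
#'   one-vs-rest log hazards.
#' @export
extreme_cohort_hr <- function(calls, clinical, stage_filter = NULL,
                              exclude_datasets = NULL) {
  df <- merge(calls, clinical, by = "sample_id")
  if (!is.null(stage_filter)) {
    if (is.null(df$stage)) stop("stage filter requested but clinical table has no stage")
    df <- df[!is.na(df$stage) & df$stage %in% stage_filter, , drop = FALSE]
  }
  if (!is.null(exclude_datasets) && !is.null(df$dataset))
    df <- df[!df$dataset %in% exclude_datasets, , drop = FALSE]
  df <- df[!is.na(df$label) & !is.na(df$rfs_time) & !is.na(df$rfs_event), , drop = FALSE]
  labs <- unique(df$label)
  if (length(labs) < 2L)
    stop("fewer than 2 classified labels after exclusions",
         if (nrow(df) == 0L) " (no samples left)" else
           paste0(" (only '", labs, "')"))
  lh <- vapply(labs, function(L) {
    ind <- factor(df$label == L, levels = c(FALSE, TRUE))
    if (sum(df$rfs_event[df$label == L]) == 0 ||
        sum(df$rfs_event[df$label != L]) == 0) return(NA_real_)
    fit <- survival::coxph(survival::Surv(df$rfs_time, df$rfs_event) ~ ind,
                           ties = "efron")
    unname(stats::coef(fit))
  }, 0)
  if (all(is.na(lh))) stop("no label with events on both sides of the one-vs-rest split")
  best <- labs[which.min(lh)]; worst <- labs[which.max(lh)]
  keep <- df$label %in% c(best, worst)
  res <- cox_two_group(df$rfs_time[keep], df$rfs_event[keep],
                       factor(df$label[keep], levels = c(best, worst)),
                       comparison = paste0(calls$classifier[1L], ": ",
                                           worst, " vs ", best))
  attr(res, "label_rank") <- sort(lh)
  res
}

#' Univariate median-split survival screen over genes
#'
#' For each gene, splits the cohort at the gene's median expression (ties
#' to the low group) and fits a two-group Cox model. Constant genes yield
#' NA rows and are excluded from the significant-proportion denominators.
#'
#' @param em A `crc_matrix`.
#' @param clinical Clinical table (`sample_id`, `rfs_time`, `rfs_event`).
#' @param genes Gene symbols to screen (default: all matrix rows).
#' @return Data frame `gene`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `n_low`, `n_high`; attributes `prop_p05` and `prop_p01`
#'   hold the proportions of screened genes significant at 0.05 / 0.01.
#' @export
univariate_gene_screen <- function(em, clinical, genes = rownames(em$values)) {
  common <- intersect(colnames(em$values), clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  ok <- !is.na(cl$rfs_time) & !is.na(cl$rfs_event)
  common <- common[ok]; cl <- cl[ok, , drop = FALSE]
  genes <- intersect(genes, rownames(em$values))
  rows <- lapply(genes, function(g) {
    v <- em$values[g, common]
    if (length(unique(v[!is.na(v)])) < 2L)
      return(data.frame(gene = g, hazard_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        n_low = NA_integer_, n_high = NA_integer_))
    grp <- factor(ifelse(v > stats::median(v, na.rm = TRUE), "high", "low"),
                  levels = c("low", "high"))
    res <- tryCatch(cox_two_group(cl$rfs_time, cl$rfs_event, grp, comparison = g),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(gene = g, hazard_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        n_low = NA_integer_, n_high = NA_integer_))
    data.frame(gene = g, hazard_ratio = res$hazard_ratio, ci_low = res$ci_low,
               ci_high = res$ci_high, p_value = res$p_value,
               n_low = res$n[1L], n_high = res$n[2L])
  })
  out <- do.call(rbind, rows)
  p <- out$p_value[!is.na(out$p_value)]
  attr(out, "prop_p05") <- if (length(p)) mean(p < 0.05) else NA_real_
  attr(out, "prop_p01") <- if (length(p)) mean(p < 0.01) else NA_real_
  out
}

#' Per-signature screen summary and its correlation with classifier power
#'
#' `screen_by_signature()` runs the univariate gene screen restricted to
#' each signature's gene list and reports the proportion of its genes
#' significant at 0.05 and 0.01. `spearman_prop_vs_hr()` relates those
#' proportions to the hazard ratios the classifiers achieve (Spearman rank
#' correlation).
#'
#' @param em,clinical As in [univariate_gene_screen()].
#' @param signatures List of `crc_signature` objects.
#' @return Data frame `classifier`, `n_genes_screened`, `prop_p05`,
#'   `prop_p01`.
#' @export
screen_by_signature <- function(em, clinical, signatures) {
  rows <- lapply(signatures, function(sig) {
    sc <- univariate_gene_screen(em, clinical,
                                 genes = intersect(sig$genes$symbol,
                                                   rownames(em$values)))
    data.frame(classifier = sig$name,
               n_genes_screened = sum(!is.na(sc$p_value)),
               prop_p05 = attr(sc, "prop_p05"),
               prop_p01 = attr(sc, "prop_p01"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname screen_by_signature
#' @param proportions Per-classifier proportions of significant genes.
#' @param hazard_ratios Per-classifier best-vs-worst hazard ratios (same
#'   order).
#' @return List `rho`, `p_value` from the Spearman rank correlation.
#' @export
spearman_prop_vs_hr <- function(proportions, hazard_ratios) {
  ct <- suppressWarnings(stats::cor.test(proportions, hazard_ratios,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Multivariate Cox adjustment of a classifier
#'
#' Fits a proportional-hazards model with the classifier's (two-level)
#' label plus clinical covariates — typically MSI status, gender and the
#' expression of the proliferation marker MKI67 and of CDX2 — and reports
#' every term. Rows with any missing covariate are deleted listwise (the
#' dropped count is reported); the covariates must be available for at
#' least half of the classified samples, and exactly collinear covariates
#' raise an error naming the pair.
#'
#' @param calls Subtype call data frame with two distinct non-NA labels
#'   (e.g. restricted to the best/worst cohorts).
#' @param clinical Clinical table; covariate columns are looked up here.
#' @param covariates Character vector of clinical covariate columns.
#' @param expr_covariates Optional named list of per-sample numeric vectors
#'   (e.g. `list(mki67_expr = ..., cdx2_expr = ...)`), named by sample id.
#' @return List: `terms` (data frame `term`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `p_value`), `n_used`, `n_dropped`.
#' @export
multivariate_cox <- function(calls, clinical, covariates = c("msi", "gender"),
                             expr_covariates = list()) {
  df <- merge(calls[!is.na(calls$label), c("sample_id", "label")],
              clinical, by = "sample_id")
  if (length(unique(df$label)) != 2L)
    stop("classifier term must have exactly 2 labels; restrict calls to the extreme cohorts")
  miss <- setdiff(covariates, names(df))
  if (length(miss)) stop("covariate column(s) absent from clinical table: ",
                         paste(miss, collapse = ", "))
  for (nm in names(expr_covariates))
    df[[nm]] <- expr_covariates[[nm]][df$sample_id]
  vars <- c(covariates, names(expr_covariates))
  complete <- stats::complete.cases(df[, c("rfs_time", "rfs_event", "label", vars)])
  if (mean(complete) < 0.5)
    stop("covariates available for fewer than 50% of classified samples")
  n_dropped <- sum(!complete)
  if (n_dropped) message(n_dropped, " row(s) with missing covariates dropped")
  df <- df[complete, , drop = FALSE]

  df$label <- factor(df$label)
  for (v in covariates) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  form <- stats::as.formula(paste("survival::Surv(rfs_time, rfs_event) ~ label +",
                                  paste(vars, collapse = " + ")))
  mm <- stats::model.matrix(stats::as.formula(paste("~ label +",
                                                    paste(vars, collapse = " + "))), df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    cc <- stats::cor(mm[, -1L, drop = FALSE])
    pair <- which(abs(cc) > 0.9999 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(pair))
      stop("collinear covariates: ", colnames(cc)[pair[1L, 1L]], " and ",
           colnames(cc)[pair[1L, 2L]])
    stop("rank-deficient covariate matrix")
  }
  fit <- survival::coxph(form, data = df, ties = "efron")
  co <- stats::coef(fit); se <- sqrt(diag(fit$var))
  list(terms = data.frame(term = names(co),
                          hazard_ratio = exp(unname(co)),
                          ci_low = exp(unname(co) - stats::qnorm(0.975) * se),
                          ci_high = exp(unname(co) + stats::qnorm(0.975) * se),
                          p_value = 2 * stats::pnorm(-abs(unname(co) / se)),
                          stringsAsFactors = FALSE),
       n_used = nrow(df), n_dropped = n_dropped)
}
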