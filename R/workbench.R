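#' Run the full cross-validation benchmark
#'
#' Orchestrates the pipeline — classify every signature, classifier
#' concordance (Cramer's V and per-prognosis-label agreement), gene-list
#' overlap, gene-score ranking, best-vs-worst survival benchmarking,
#' per-signature univariate gene screens, and (optionally) cell-line
#' consensus assignment — and writes one TSV per artifact into the output
#' directory, stamped with the seed and a hash of the configuration. Any
#' stage failure aborts with the stage name and removes partial outputs.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{matrix}{`crc_matrix` or TSV path ([load_matrix()]).}
#'     \item{clinical}{data frame or TSV path ([load_clinical()]).}
#'     \item{signatures}{named list of `crc_signature` or a bundle path
#'       ([load_signature_config()]).}
#'     \item{models}{optional named list of trained models.}
#'     \item{stage_filter}{optional stage subset for survival (e.g.
#'       `c("II", "III")`).}
#'     \item{exclude_training}{apply each signature's `training_sets`
#'       exclusion in the survival benchmark (default TRUE).}
#'     \item{cellline}{optional list with `matrix`, `line_of_array` and
#'       optionally `mutations`.}
#'     \item{out_dir}{output directory (created).}
#'     \item{seed}{integer seed.}
#'   }
#' @return Invisibly, a named list of the in-memory results
#'   (`calls`, `cramers_v`, `prognosis_concordance`, `overlap`,
#'   `gene_scores`, `forest`, `screen`, `cellline`, `files`).
#' @export
run_benchmark <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  set.seed(seed)
  em <- stage("load_matrix", {
    if (inherits(config$matrix, "crc_matrix")) config$matrix else
      load_matrix(config$matrix)
  })
  clinical <- stage("load_clinical", {
    cl <- if (is.data.frame(config$clinical)) config$clinical else
      load_clinical(config$clinical)
    validate_clinical(cl, em)
  })
  signatures <- stage("load_signatures", {
    if (is.character(config$signatures))
      load_signature_config(config$signatures) else config$signatures
  })
  models <- config$models %||% list()

  calls <- stage("classify", classify_cohort(em, signatures, models))
  emit(calls, "calls.tsv")

  cv <- stage("concordance", concordance_matrix(calls))
  emit(data.frame(classifier = rownames(cv), cv, check.names = FALSE),
       "cramers_v.tsv")

  prog <- stage("prognosis_concordance", {
    rows <- list()
    nm <- names(signatures)
    for (pr in c("good", "bad")) {
      withlab <- Filter(function(s) pr %in% s$labels$prognosis, signatures)
      ns <- names(withlab)
      if (length(ns) < 2L) next
      for (i in seq_len(length(ns) - 1L)) for (j in (i + 1L):length(ns)) {
        la <- withlab[[ns[i]]]$labels
        lb <- withlab[[ns[j]]]$labels
        rows[[length(rows) + 1L]] <- data.frame(
          prognosis = pr, classifier_a = ns[i], classifier_b = ns[j],
          concordance = suppressWarnings(prognosis_label_concordance(
            calls[calls$classifier == ns[i], ],
            calls[calls$classifier == ns[j], ],
            la$label[la$prognosis == pr][1L],
            lb$label[lb$prognosis == pr][1L])),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(prognosis = character(), classifier_a = character(),
                 classifier_b = character(), concordance = numeric())
  })
  emit(prog, "prognosis_concordance.tsv")

  if (length(signatures) >= 2L) {
    ov <- stage("overlap", signature_overlap_matrix(signatures))
    emit(data.frame(classifier = rownames(ov), ov, check.names = FALSE),
         "overlap.tsv")
  } else ov <- NULL

  gs <- stage("gene_scores", gene_score_ranking(signatures))
  emit(gs, "gene_scores.tsv")

  forest <- stage("survival", {
    rows <- lapply(signatures, function(sig) {
      res <- tryCatch(
        extreme_cohort_hr(calls[calls$classifier == sig$name, ], clinical,
                          stage_filter = config$stage_filter,
                          exclude_datasets = if (isTRUE(config$exclude_training %||% TRUE))
                            sig$training_sets else NULL),
        error = function(e) e)
      if (inherits(res, "error"))
        data.frame(classifier = sig$name, comparison = NA, hazard_ratio = NA,
                   ci_low = NA, ci_high = NA, p_value = NA, n_best = NA,
                   n_worst = NA, note = conditionMessage(res))
      else
        data.frame(classifier = sig$name, comparison = res$comparison,
                   hazard_ratio = res$hazard_ratio, ci_low = res$ci_low,
                   ci_high = res$ci_high, p_value = res$p_value,
                   n_best = res$n[1L], n_worst = res$n[2L], note = "")
    })
    do.call(rbind, rows)
  })
  emit(forest, "forest.tsv")

  screen <- stage("gene_screen", {
    sc <- screen_by_signature(em, clinical, signatures)
    ok <- !is.na(sc$prop_p05) & !is.na(forest$hazard_ratio)
    if (sum(ok) >= 3L) {
      sp <- spearman_prop_vs_hr(sc$prop_p05[ok], forest$hazard_ratio[ok])
      attr(sc, "spearman_rho") <- sp$rho
      attr(sc, "spearman_p") <- sp$p_value
    }
    sc
  })
  emit(screen, "univariate_screen.tsv")

  cellline <- NULL
  if (!is.null(config$cellline)) {
    cellline <- stage("cellline", {
      panel <- classify_cellline_panel(config$cellline$matrix,
                                       config$cellline$line_of_array,
                                       signatures, models)
      assign <- panel$assignments
      if (!is.null(config$cellline$mutations))
        assign <- annotate_mutations(assign, config$cellline$mutations)
      assign
    })
    emit(cellline, "cellline.tsv")
    prev <- stage("cellline_prevalence",
                  subtype_prevalence_vs_models(calls, cellline))
    emit(prev, "cellline_prevalence.tsv")
  }

  stage("run_info", {
    cfg_path <- file.path(out_dir, "config_used.yaml")
    cfg_txt <- list(seed = seed,
                    stage_filter = config$stage_filter,
                    exclude_training = isTRUE(config$exclude_training %||% TRUE),
                    signatures = names(signatures),
                    n_samples = ncol(em$values), n_genes = nrow(em$values))
    yaml::write_yaml(cfg_txt, cfg_path)
    written <<- c(written, cfg_path)
    emit(data.frame(key = c("seed", "config_md5", "n_samples", "n_genes"),
                    value = c(seed, unname(tools::md5sum(cfg_path)),
                              ncol(em$values), nrow(em$values))),
         "run_info.tsv")
  })

  invisible(list(calls = calls, cramers_v = cv, prognosis_concordance = prog,
                 overlap = ov, gene_scores = gs, forest = forest,
                 screen = screen, cellline = cellline, files = written))
}
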