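#' Declarative classifier signature
#'
#' A signature bundles everything needed to run one published colon-cancer
#' classifier: its gene list (with per-gene risk direction and optional
#' weight), the classification rule and its parameters, the output labels
#' with their prognosis annotation, optional housekeeping genes, and the
#' dataset tags of the classifier's original training cohort (excluded at
#' validation time).
#'
#' @param name Classifier name.
#' @param genes Data frame with columns `symbol`, `direction`
#'   (`up_is_risk`, `down_is_risk`, `unsigned`) and optionally `weight`
#'   (required by weighted rules, must be absent/NA otherwise) and `model`
#'   (sub-model tag for `dual_median` rules).
#' @param rule A [rule_spec()].
#' @param labels Data frame with columns `label` and `prognosis`
#'   (`good`, `bad`, `intermediate`, `unannotated`).
#' @param housekeeping Optional character vector of reference genes.
#' @param delta_ct Optional list describing an RT-PCR-style delta-Ct
#'   pre-transform: `constant` (e.g. -15), `mean_mode`
#'   (`arithmetic`/`geometric`); applied with `housekeeping` before scoring.
#' @param training_sets Optional character vector of dataset tags to exclude
#'   when benchmarking survival.
#' @return Object of class `crc_signature`.
#' @export
crc_signature <- function(name, genes, rule, labels, housekeeping = NULL,
                          delta_ct = NULL, training_sets = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.data.frame(genes))
  if (nrow(genes) == 0L) stop("signature '", name, "': empty gene list")
  if (is.null(genes$direction)) genes$direction <- "unsigned"
  ok_dir <- c("up_is_risk", "down_is_risk", "unsigned")
  if (!all(genes$direction %in% ok_dir))
    stop("signature '", name, "': invalid direction(s)")
  if (is.null(genes$weight)) genes$weight <- NA_real_
  genes$symbol <- as.character(genes$symbol)
  if (anyDuplicated(genes$symbol))
    stop("signature '", name, "': duplicated gene symbol")
  if (!is.data.frame(labels) || !all(c("label", "prognosis") %in% names(labels)))
    stop("signature '", name, "': labels must have columns label, prognosis")
  labels$label <- as.character(labels$label)
  ok_prog <- c("good", "bad", "intermediate", "unannotated")
  if (!all(labels$prognosis %in% ok_prog))
    stop("signature '", name, "': invalid prognosis annotation")

  sig <- structure(
    list(name = name, genes = genes, rule = rule, labels = labels,
         housekeeping = housekeeping, delta_ct = delta_ct,
         training_sets = training_sets),
    class = "crc_signature")
  assert_signature(sig)
  sig
}

#' Classification rule specification
#'
#' @param kind One of `linear_cutoff`, `product_ratio`, `tally`,
#'   `signature_mean_split`, `group_mean_compare`, `dual_median`,
#'   `trained_model`.
#' @param ... Kind-specific parameters:
#' \describe{
#'   \item{linear_cutoff}{`intercept` (default 0), `cutoff_mode`
#'     (`fixed`/`cohort_median`/`tertile`), `cutoffs` (fixed mode).}
#'   \item{product_ratio}{`terms`: list of `list(num=, den=, sign=)` entries,
#'     score = sum sign * abs(prod(num)/den); `housekeeping_adjust`
#'     (subtract the mean housekeeping level first); `cutoff_mode`.}
#'   \item{tally}{`reference` (`median` or `percentile`), `hi`/`lo`
#'     percentile bounds (risk cut for up/down genes), `threshold` (risk
#'     call at >= threshold positive genes; `NULL` means the tally count
#'     itself is the label, as in the 0/1/2/3 scheme).}
#'   \item{signature_mean_split}{`cutoff_mode` (`cohort_median`/`tertile`).}
#'   \item{group_mean_compare}{`g1`, `g2`: the two gene partitions.}
#'   \item{dual_median}{two weighted sub-scores (gene `model` column `a`/`b`),
#'     high only when both exceed their own cohort medians.}
#'   \item{trained_model}{`engine`, `confidence_floor` in \[0,1\].}
#' }
#' @return List of class `crc_rule`.
#' @export
rule_spec <- function(kind, ...) {
  kinds <- c("linear_cutoff", "product_ratio", "tally", "signature_mean_split",
             "group_mean_compare", "dual_median", "trained_model")
  if (!kind %in% kinds) stop("unknown rule kind: ", kind)
  structure(c(list(kind = kind), list(...)), class = "crc_rule")
}

rule_needs_weights <- function(kind)
  kind %in% c("linear_cutoff", "dual_median")

n_labels_for_rule <- function(sig) {
  r <- sig$rule
  switch(r$kind,
    linear_cutoff = ,
    product_ratio = ,
    signature_mean_split = switch(r$cutoff_mode %||% "cohort_median",
                                  fixed = length(r$cutoffs) + 1L,
                                  cohort_median = 2L, tertile = 3L),
    tally = if (is.null(r$threshold)) nrow(sig$genes) + 1L else 2L,
    group_mean_compare = 2L,
    dual_median = 2L,
    trained_model = NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_signature <- function(sig) {
  r <- sig$rule
  if (!inherits(r, "crc_rule")) stop("rule must be built with rule_spec()")
  need_w <- rule_needs_weights(r$kind)
  has_w <- !is.na(sig$genes$weight)
  if (need_w && !all(has_w))
    stop("signature '", sig$name, "': rule '", r$kind, "' requires a weight for every gene")
  if (!need_w && any(has_w))
    stop("signature '", sig$name, "': rule '", r$kind, "' does not take gene weights")
  if (r$kind == "tally") {
    ref <- r$reference %||% "median"
    if (!ref %in% c("median", "percentile")) stop("tally reference must be median or percentile")
    if (ref == "percentile") {
      hi <- r$hi %||% 80; lo <- r$lo %||% 20
      if (!(hi > 0 && hi < 100 && lo > 0 && lo < 100))
        stop("percentile bounds must lie in (0, 100)")
    }
    if (!is.null(r$threshold) && r$threshold > nrow(sig$genes))
      stop("signature '", sig$name, "': tally threshold ", r$threshold,
           " exceeds gene count ", nrow(sig$genes))
  }
  if (r$kind == "group_mean_compare") {
    if (is.null(r$g1) || is.null(r$g2) || !length(r$g1) || !length(r$g2))
      stop("group_mean_compare needs non-empty partitions g1 and g2")
    if (!all(c(r$g1, r$g2) %in% sig$genes$symbol))
      stop("partition genes must appear in the signature gene list")
  }
  if (r$kind == "dual_median") {
    m <- sig$genes$model
    if (is.null(m) || !setequal(unique(m), c("a", "b")))
      stop("dual_median needs a gene 'model' column with values a and b")
  }
  if (r$kind == "product_ratio" && is.null(r$terms))
    stop("product_ratio rule needs 'terms'")
  if (r$kind == "trained_model") {
    fl <- r$confidence_floor %||% 0
    if (fl < 0 || fl > 1) stop("confidence_floor must lie in [0, 1]")
  }
  nl <- n_labels_for_rule(sig)
  if (!is.na(nl) && nrow(sig$labels) != nl)
    stop("signature '", sig$name, "': rule '", r$kind, "' produces ", nl,
         " label(s) but ", nrow(sig$labels), " are declared")
  invisible(sig)
}

#' @export
print.crc_signature <- function(x, ...) {
  cat(sprintf("crc_signature '%s': %d gene(s), rule %s, labels {%s}\n",
              x$name, nrow(x$genes), x$rule$kind,
              paste(x$labels$label, collapse = ", ")))
  invisible(x)
}

# ---- built-in signatures (constants from the original method descriptions) ----

#' Built-in classifier signatures
#'
#' Signatures whose gene lists and parameters are fully specified by the
#' original method descriptions ship ready to run: the five-term hypoxia
#' score CCHS (the source describes it as a six-gene model but prints five
#' gene terms plus an intercept; the printed five-term formula is
#' implemented), the three-gene Yuen3 tally, the seven-gene ColoGuidePro
#' tally, and the five-gene Oncodefender product-ratio score. Classifiers
#' whose gene lists were published only as supplements (CIN25, Chang95,
#' ColoGuideEx, Merlos, ...) are built from user-supplied lists via the
#' `signature_*()` constructors or a config file.
#'
#' @return Named list of `crc_signature` objects.
#' @export
builtin_signatures <- function() {
  cchs <- crc_signature(
    "CCHS",
    data.frame(symbol = c("BCCIP", "BNIP3L", "GADD45B", "INSIG2", "TP53"),
               direction = c("up_is_risk", "down_is_risk", "up_is_risk",
                             "up_is_risk", "down_is_risk"),
               weight = c(0.543, -0.416, 0.596, 0.538, -0.177)),
    rule_spec("linear_cutoff", intercept = 1.301, cutoff_mode = "fixed",
              cutoffs = 4.526),
    data.frame(label = c("low_risk", "high_risk"),
               prognosis = c("good", "bad")))

  yuen3 <- crc_signature(
    "Yuen3",
    data.frame(symbol = c("TAZ", "AXL", "CTGF"), direction = "up_is_risk"),
    rule_spec("tally", reference = "median", threshold = NULL),
    data.frame(label = c("0", "1", "2", "3"),
               prognosis = c("good", "intermediate", "intermediate", "bad")))

  cologuidepro <- crc_signature(
    "ColoGuidePro",
    data.frame(symbol = c("DMBT1", "NT5E", "SEMA3A", "WNT11",
                          "CXCL9", "OLFM4", "UGT2B17"),
               direction = c(rep("up_is_risk", 4L), rep("down_is_risk", 3L))),
    rule_spec("tally", reference = "median", threshold = 3L),
    data.frame(label = c("good_prognosis", "poor_prognosis"),
               prognosis = c("good", "bad")))

  oncodefender <- crc_signature(
    "Oncodefender",
    data.frame(symbol = c("BMI1", "VEGFA", "H3F3B", "ETV6", "RPS10"),
               direction = "unsigned"),
    rule_spec("product_ratio",
              terms = list(list(num = c("BMI1", "VEGFA"), den = "H3F3B", sign = 1),
                           list(num = c("ETV6", "H3F3B"), den = "RPS10", sign = -1)),
              housekeeping_adjust = TRUE, cutoff_mode = "cohort_median"),
    data.frame(label = c("low_risk", "high_risk"), prognosis = c("good", "bad")),
    housekeeping = c("B2M", "GUSB", "POLR2L", "PSMB6", "UBC"))

  list(CCHS = cchs, Yuen3 = yuen3, ColoGuidePro = cologuidepro,
       Oncodefender = oncodefender)
}

#' Recurrence-score and relapse-hazard-score defaults
#'
#' The RT-PCR-style classifiers that need externally published weights
#' (Oncotype DX colon recurrence score; the seven-gene relapse hazard score
#' V7RHS) ship only their fixed rule parameters as built-in defaults: the
#' delta-Ct constant (-15), the recurrence-score cutoffs (low < 30,
#' 30--40 intermediate, > 40 high), the V7RHS cutoff (> 0 is high risk) and
#' the V7RHS housekeeping panel (ACTB, HMBS, RPL13A). Gene lists and weights
#' are config-supplied.
#'
#' @return Named list of defaults.
#' @export
rtpcr_rule_defaults <- function() {
  list(odxcolon = list(delta_ct_constant = -15, cutoff_low = 30, cutoff_high = 40),
       v7rhs = list(delta_ct_constant = -15, cutoff = 0,
                    housekeeping = c("ACTB", "HMBS", "RPL13A")))
}

#' Construct an Oncotype-DX-colon-style recurrence score signature
#'
#' Applies the built-in rule defaults (delta-Ct constant -15; recurrence
#' score cut at 30 and 40, both boundaries intermediate) to user-supplied
#' gene weights and housekeeping genes.
#'
#' @param genes Data frame with `symbol`, `direction`, `weight`.
#' @param housekeeping Reference gene panel for the delta-Ct transform.
#' @param intercept Recurrence-score intercept (default 0).
#' @return A `crc_signature` named `ODXcolon`.
#' @export
signature_odxcolon <- function(genes, housekeeping, intercept = 0) {
  d <- rtpcr_rule_defaults()$odxcolon
  crc_signature("ODXcolon", genes,
                rule_spec("linear_cutoff", intercept = intercept,
                          cutoff_mode = "fixed",
                          cutoffs = c(d$cutoff_low, d$cutoff_high)),
                data.frame(label = c("low", "intermediate", "high"),
                           prognosis = c("good", "intermediate", "bad")),
                housekeeping = housekeeping,
                delta_ct = list(constant = d$delta_ct_constant,
                                mean_mode = "arithmetic"))
}

#' Construct a V7RHS-style relapse hazard score signature
#'
#' @param genes Data frame with `symbol`, `direction`, `weight` (the seven
#'   signature genes and their published weights).
#' @param intercept Score intercept (default 0).
#' @return A `crc_signature` named `V7RHS` with the built-in housekeeping
#'   panel and the `> 0 = high risk` cutoff.
#' @export
signature_v7rhs <- function(genes, intercept = 0) {
  d <- rtpcr_rule_defaults()$v7rhs
  crc_signature("V7RHS", genes,
                rule_spec("linear_cutoff", intercept = intercept,
                          cutoff_mode = "fixed", cutoffs = d$cutoff),
                data.frame(label = c("low_risk", "high_risk"),
                           prognosis = c("good", "bad")),
                housekeeping = d$housekeeping,
                delta_ct = list(constant = d$delta_ct_constant,
                                mean_mode = "arithmetic"))
}

#' Convenience constructors for generic rule signatures
#'
#' `signature_mean()` builds a signature-mean classifier (median or tertile
#' split of the mean expression, as used by the chromosomal-instability
#' score and similar average-expression signatures); `signature_tally()`
#' builds per-gene tally classifiers (percentile or median references);
#' `signature_group_means()` builds the two-partition mean comparison.
#'
#' @param name Classifier name.
#' @param symbols Gene symbols.
#' @param directions Per-gene risk directions (recycled).
#' @param cutoff_mode `"cohort_median"` or `"tertile"`.
#' @param labels,prognosis Output labels and their prognosis annotations
#'   (defaults supplied per rule).
#' @param training_sets Dataset tags of the original training cohort.
#' @return A `crc_signature`.
#' @export
signature_mean <- function(name, symbols, directions = "up_is_risk",
                           cutoff_mode = c("cohort_median", "tertile"),
                           labels = NULL, prognosis = NULL,
                           training_sets = NULL) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (is.null(labels))
    labels <- if (cutoff_mode == "cohort_median") c("low", "high") else
      c("low", "intermediate", "high")
  if (is.null(prognosis))
    prognosis <- if (length(labels) == 2L) c("good", "bad") else
      c("good", "intermediate", "bad")
  crc_signature(name,
                data.frame(symbol = symbols,
                           direction = rep_len(directions, length(symbols))),
                rule_spec("signature_mean_split", cutoff_mode = cutoff_mode),
                data.frame(label = labels, prognosis = prognosis),
                training_sets = training_sets)
}

#' @rdname signature_mean
#' @param reference `"median"` or `"percentile"` per-gene risk reference.
#' @param threshold Risk tally threshold (`NULL`: the count is the label).
#' @param hi,lo Percentile bounds for up/down risk genes.
#' @export
signature_tally <- function(name, symbols, directions = "up_is_risk",
                            reference = c("median", "percentile"),
                            threshold = NULL, hi = 80, lo = 20,
                            labels = NULL, prognosis = NULL,
                            training_sets = NULL) {
  reference <- match.arg(reference)
  if (is.null(labels))
    labels <- if (is.null(threshold)) as.character(0:length(symbols)) else
      c("low_risk", "high_risk")
  if (is.null(prognosis))
    prognosis <- if (is.null(threshold))
      c("good", rep("intermediate", length(symbols) - 1L), "bad") else
      c("good", "bad")
  crc_signature(name,
                data.frame(symbol = symbols,
                           direction = rep_len(directions, length(symbols))),
                rule_spec("tally", reference = reference, threshold = threshold,
                          hi = hi, lo = lo),
                data.frame(label = labels, prognosis = prognosis),
                training_sets = training_sets)
}

#' @rdname signature_mean
#' @param g1,g2 Gene partitions compared by their per-sample means;
#'   `mean(g1) < mean(g2)` yields the second label.
#' @export
signature_group_means <- function(name, g1, g2,
                                  labels = c("wild-type-like", "BRAF-mutant-like"),
                                  prognosis = c("unannotated", "unannotated"),
                                  training_sets = NULL) {
  crc_signature(name,
                data.frame(symbol = c(g1, g2), direction = "unsigned"),
                rule_spec("group_mean_compare", g1 = g1, g2 = g2),
                data.frame(label = labels, prognosis = prognosis),
                training_sets = training_sets)
}

# ---- config I/O ----

sig_to_list <- function(sig) {
  r <- unclass(sig$rule)
  list(name = sig$name,
       genes = lapply(seq_len(nrow(sig$genes)), function(i) {
         g <- as.list(sig$genes[i, , drop = FALSE])
         g <- lapply(g, function(v) if (is.factor(v)) as.character(v) else v)
         if (is.na(g$weight)) g$weight <- NULL
         g
       }),
       rule = r[!vapply(r, is.null, TRUE)],
       labels = lapply(seq_len(nrow(sig$labels)), function(i)
         list(label = sig$labels$label[i], prognosis = sig$labels$prognosis[i])),
       housekeeping = sig$housekeeping,
       delta_ct = sig$delta_ct,
       training_sets = sig$training_sets)
}

list_to_sig <- function(x) {
  genes <- data.frame(
    symbol = vapply(x$genes, function(g) g$symbol, ""),
    direction = vapply(x$genes, function(g) g$direction %||% "unsigned", ""),
    weight = vapply(x$genes, function(g) as.numeric(g$weight %||% NA_real_), 0),
    stringsAsFactors = FALSE)
  if (!is.null(x$genes[[1L]]$model))
    genes$model <- vapply(x$genes, function(g) g$model, "")
  labels <- data.frame(
    label = vapply(x$labels, function(l) as.character(l$label), ""),
    prognosis = vapply(x$labels, function(l) l$prognosis, ""),
    stringsAsFactors = FALSE)
  rule <- do.call(rule_spec, x$rule)
  crc_signature(x$name, genes, rule, labels,
                housekeeping = unlist(x$housekeeping),
                delta_ct = x$delta_ct,
                training_sets = unlist(x$training_sets))
}

#' Read / write signature bundles
#'
#' Signature bundles are YAML files holding a list of signature definitions
#' under the top-level key `signatures`; the schema mirrors the
#' [crc_signature()] fields. Loading validates every signature.
#'
#' @param path YAML file path.
#' @return `load_signature_config()`: named list of `crc_signature`;
#'   `write_signature_config()`: the path, invisibly.
#' @examples
#' bundle <- system.file("extdata", "example_signatures.yaml",
#'                       package = "crcbench")
#' names(load_signature_config(bundle))
#' @export
load_signature_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$signatures)) stop("config has no 'signatures' key: ", path)
  sigs <- lapply(cfg$signatures, list_to_sig)
  names(sigs) <- vapply(sigs, function(s) s$name, "")
  sigs
}

#' @rdname load_signature_config
#' @param signatures List of `crc_signature` objects.
#' @export
write_signature_config <- function(signatures, path) {
  yaml::write_yaml(list(signatures = lapply(signatures, sig_to_list)), path)
  invisible(path)
}

#' Gene coverage of a signature on a matrix
#'
#' Reports the fraction of signature genes measurable in the matrix; a
#' signature is evaluable when coverage reaches the floor. The floor
#' defaults to 0.8: classifiers are expected to degrade gracefully on
#' reduced-gene platforms (the compound-covariate classifier, for instance,
#' runs on the probe subset shared between array generations), but below
#' 80\% coverage a call is no longer considered faithful to the published
#' rule.
#'
#' @param sig A `crc_signature`.
#' @param em A `crc_matrix`.
#' @param floor Minimum coverage for the signature to be evaluable.
#' @return List: `coverage`, `present`, `missing`, `evaluable`.
#' @export
validate_signature <- function(sig, em, floor = 0.8) {
  present <- intersect(sig$genes$symbol, rownames(em$values))
  missing <- setdiff(sig$genes$symbol, present)
  cov <- length(present) / nrow(sig$genes)
  list(coverage = cov, present = present, missing = missing,
       evaluable = cov >= floor)
}
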