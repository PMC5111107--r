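# shared fixture builders (all data generated in code)

toy_em <- function(values, genes = NULL, samples = NULL, dataset = "toy") {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, dataset = dataset)
}

# planted two-class expression data: first `n_inf` genes shifted in class B
planted_two_class <- function(n_per = 20L, n_genes = 50L, n_inf = 5L,
                              shift = 3, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per
  m <- matrix(stats::rnorm(n_genes * n), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  lab <- rep(c("A", "B"), each = n_per)
  m[seq_len(n_inf), lab == "B"] <- m[seq_len(n_inf), lab == "B"] + shift
  list(em = expression_matrix(m), labels = lab)
}

# minimal calls data frame
calls_df <- function(sample_id, label, classifier = "clf") {
  data.frame(sample_id = sample_id, classifier = classifier,
             label = as.character(label), score = NA_real_,
             confidence = NA_real_, stringsAsFactors = FALSE)
}

# clinical frame from raw vectors
clin_df <- function(sample_id, time, event, stage = NULL, dataset = NULL) {
  df <- data.frame(sample_id = sample_id, rfs_time = time, rfs_event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(stage)) df$stage <- stage
  if (!is.null(dataset)) df$dataset <- dataset
  df
}
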