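#' Trainable subtype classifier engines
#'
#' Re-trainable engines behind the centroid-style classifiers: nearest
#' centroid (`train_nearest_centroid`), nearest shrunken centroid / PAM
#' (`train_shrunken_centroid`), compound covariate predictor
#' (`train_compound_covariate`), meta-gene linear discriminant
#' (`train_metagene_lda`) and reference engines (`train_reference_model`:
#' KNN and linear maximum-margin). All return objects of class `crc_model`
#' with a common [predict.crc_model()] method emitting subtype calls.
#'
#' @param em A `crc_matrix` of training samples.
#' @param labels Class label per training sample (character/factor), aligned
#'   with the matrix columns or named by sample id.
#' @param metric Distance used at prediction time: `"euclidean"` or
#'   `"correlation"` (one minus Pearson; the convention for centroid
#'   correlation predictors).
#' @param name Classifier name stamped on predictions.
#' @return A `crc_model`.
#' @name trained-engines
NULL

align_labels <- function(em, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(em$values)]
  if (length(labels) != ncol(em$values))
    stop("labels must align with matrix samples")
  if (anyNA(labels)) stop("NA training label(s)")
  factor(as.character(labels))
}

check_classes <- function(f, min_per_class = 2L) {
  tab <- table(f)
  if (any(tab == 0L)) stop("class with 0 samples: ",
                           paste(names(tab)[tab == 0L], collapse = ", "))
  if (nlevels(f) < 2L) stop("need at least 2 classes, got ", nlevels(f))
  if (any(tab < min_per_class))
    stop("class(es) with fewer than ", min_per_class, " samples: ",
         paste(names(tab)[tab < min_per_class], collapse = ", "))
  invisible(tab)
}

new_crc_model <- function(engine, name, genes, classes, ...) {
  structure(list(engine = engine, name = name, genes = genes,
                 classes = classes, ...),
            class = c(paste0("crc_", engine, "_model"), "crc_model"))
}

#' @export
print.crc_model <- function(x, ...) {
  cat(sprintf("crc_model '%s' (%s): %d gene(s), classes {%s}\n",
              x$name, x$engine, length(x$genes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @rdname trained-engines
#' @export
train_nearest_centroid <- function(em, labels, metric = c("euclidean", "correlation"),
                                   name = "nearest_centroid") {
  metric <- match.arg(metric)
  f <- align_labels(em, labels)
  check_classes(f)
  cent <- vapply(levels(f), function(k)
    rowMeans(em$values[, f == k, drop = FALSE], na.rm = TRUE),
    numeric(nrow(em$values)))
  new_crc_model("centroid", name, rownames(em$values), levels(f),
                centroids = cent, metric = metric)
}

#' @rdname trained-engines
#' @param delta Shrinkage amount for the shrunken-centroid engine
#'   (soft-threshold applied to standardized class-vs-overall centroid
#'   differences; `delta = 0` reduces exactly to nearest centroid in
#'   standardized space).
#' @details The shrunken-centroid engine standardizes gene-level centroid
#'   contrasts by the pooled within-class standard deviation plus the
#'   median of those standard deviations (the usual stabilizing offset
#'   `s0`), soft-thresholds them by `delta`, and classifies by the
#'   standardized squared distance to the shrunken centroids with uniform
#'   class priors; per-sample class posteriors are exposed as prediction
#'   confidences.
#' @export
train_shrunken_centroid <- function(em, labels, delta = 0,
                                    name = "shrunken_centroid") {
  if (delta < 0) stop("delta must be >= 0")
  f <- align_labels(em, labels)
  check_classes(f)
  x <- em$values
  n <- ncol(x); K <- nlevels(f)
  nk <- table(f)
  overall <- rowMeans(x)
  cent <- vapply(levels(f), function(k)
    rowMeans(x[, f == k, drop = FALSE]), numeric(nrow(x)))
  ss <- rowSums(vapply(levels(f), function(k)
    rowSums((x[, f == k, drop = FALSE] - cent[, k])^2), numeric(nrow(x))))
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(cent - overall, 1L, s + s0, "/")
  d <- sweep(d, 2L, mk, "/")
  dsh <- sign(d) * pmax(abs(d) - delta, 0)
  shrunk <- overall + sweep(sweep(dsh, 2L, mk, "*"), 1L, s + s0, "*")
  dimnames(shrunk) <- list(rownames(x), levels(f))
  new_crc_model("pam", name, rownames(x), levels(f),
                centroids = shrunk, sd = s, s0 = s0, delta = delta)
}

#' @rdname trained-engines
#' @details The compound covariate predictor is two-class only: each gene's
#'   weight is its two-sample t statistic, the sample score is the
#'   weighted expression sum, and the decision threshold is the midpoint of
#'   the two class-mean scores; a sample exactly at the midpoint goes to
#'   the first (reference, lower-risk) class.
#' @export
train_compound_covariate <- function(em, labels, name = "compound_covariate") {
  f <- align_labels(em, labels)
  if (nlevels(f) != 2L) stop("compound covariate predictor requires exactly 2 classes, got ",
                             nlevels(f))
  check_classes(f)
  x <- em$values
  i1 <- f == levels(f)[1L]; i2 <- !i1
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1L, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  tstat <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  tstat[!is.finite(tstat)] <- 0
  score <- drop(crossprod(x, tstat))
  mu1 <- mean(score[i1]); mu2 <- mean(score[i2])
  new_crc_model("ccp", name, rownames(x), levels(f),
                weights = tstat, threshold = (mu1 + mu2) / 2,
                class_means = c(mu1, mu2))
}

#' @rdname trained-engines
#' @param metagene_map Named list mapping each meta-gene to its member gene
#'   symbols; the meta-gene feature is the mean of the member rows present.
#' @param ridge Ridge added to the pooled within-class covariance of the
#'   meta-gene features (default 1e-6) so singular covariances stay
#'   invertible.
#' @export
train_metagene_lda <- function(em, labels, metagene_map, ridge = 1e-6,
                               name = "metagene_lda") {
  f <- align_labels(em, labels)
  check_classes(f)
  feats <- metagene_features(em, metagene_map)
  keep <- apply(feats, 1L, function(v) length(unique(v)) > 1L)
  if (!all(keep)) {
    warning(sum(!keep), " constant meta-gene feature(s) excluded from the discriminant")
    feats <- feats[keep, , drop = FALSE]
  }
  if (nrow(feats) == 0L) stop("no usable meta-gene features")
  n <- ncol(feats); K <- nlevels(f); p <- nrow(feats)
  mu <- matrix(vapply(levels(f), function(k)
    rowMeans(feats[, f == k, drop = FALSE]), numeric(p)),
    nrow = p, dimnames = list(rownames(feats), levels(f)))
  W <- matrix(0, p, p)
  for (k in levels(f)) {
    d <- feats[, f == k, drop = FALSE] - mu[, k]
    W <- W + tcrossprod(d)
  }
  W <- W / (n - K) + ridge * diag(p)
  Winv <- solve(W)
  new_crc_model("lda", name, unique(unlist(metagene_map[rownames(feats)])),
                levels(f), metagene_map = metagene_map[rownames(feats)],
                means = mu, cov_inv = Winv, ridge = ridge)
}

metagene_features <- function(em, metagene_map) {
  feats <- lapply(names(metagene_map), function(mg) {
    members <- intersect(metagene_map[[mg]], rownames(em$values))
    if (length(members) == 0L) return(NULL)
    colMeans(em$values[members, , drop = FALSE], na.rm = TRUE)
  })
  empty <- vapply(feats, is.null, TRUE)
  if (any(empty))
    warning(sum(empty), " meta-gene(s) with no covered members dropped")
  out <- do.call(rbind, feats[!empty])
  rownames(out) <- names(metagene_map)[!empty]
  out
}

#' @rdname trained-engines
#' @param engine Reference engine: `"knn"` (majority vote; an even split is
#'   broken toward the label with the smaller aggregate neighbour
#'   distance) or `"max_margin"` (linear maximum-margin classifier, two
#'   classes, fit via a large-cost linear SVM with the separating
#'   hyperplane stored as a plain weight vector).
#' @param k Neighbourhood size for KNN (default 5; must be < n).
#' @param cost Soft-margin cost for the maximum-margin engine.
#' @export
train_reference_model <- function(em, labels, engine = c("knn", "max_margin"),
                                  k = 5L, cost = 1000, name = engine) {
  engine <- match.arg(engine)
  name <- name[1L]
  f <- align_labels(em, labels)
  check_classes(f)
  if (engine == "knn") {
    if (k >= ncol(em$values)) stop("k must be smaller than the number of training samples")
    new_crc_model("knn", name, rownames(em$values), levels(f),
                  train = em$values, train_labels = as.character(f), k = as.integer(k))
  } else {
    if (nlevels(f) != 2L) stop("max_margin engine supports exactly 2 classes")
    fit <- e1071::svm(x = t(em$values), y = f, kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # orient the hyperplane: positive decision value -> first svm level
    dec <- drop(t(em$values) %*% w + b)
    pred_pos <- levels(f)[1L]
    agree <- mean((dec > 0) == (f == pred_pos))
    if (agree < 0.5) { pos <- levels(f)[2L]; neg <- levels(f)[1L] } else {
      pos <- pred_pos; neg <- levels(f)[2L]
    }
    new_crc_model("svm", name, rownames(em$values), levels(f),
                  w = stats::setNames(w, rownames(em$values)), b = b,
                  positive = pos, negative = neg)
  }
}

#' Predict subtype calls from a trained model
#'
#' Assigns each sample the nearest / most probable class; `confidence` is
#' the class posterior (shrunken centroid, discriminant), the normalized
#' inverse distance (nearest centroid), the margin-side proximity (compound
#' covariate), or the vote fraction (KNN). Calls whose confidence falls
#' below `confidence_floor` are set to NA (the 90\%-posterior scoring rule
#' is `confidence_floor = 0.9`), and exact ties are NA by construction.
#'
#' @param object A `crc_model`.
#' @param em A `crc_matrix`; its gene space must intersect the model's.
#' @param confidence_floor Minimum confidence for a call (default: the
#'   model's own floor, else 0).
#' @param ... Unused.
#' @return Data frame of subtype calls.
#' @export
predict.crc_model <- function(object, em, confidence_floor = NULL, ...) {
  floor <- confidence_floor %||% object$confidence_floor %||% 0
  shared <- intersect(object$genes, rownames(em$values))
  if (object$engine != "lda" && length(shared) == 0L)
    stop("no overlap between model genes and matrix genes")
  x <- if (object$engine == "lda") em$values else em$values[shared, , drop = FALSE]
  samples <- colnames(em$values)

  res <- switch(object$engine,
    centroid = {
      cent <- object$centroids[shared, , drop = FALSE]
      d <- if (object$metric == "euclidean")
        sqrt(t(apply(x, 2L, function(v) colSums((cent - v)^2)))) else
        t(apply(x, 2L, function(v) 1 - stats::cor(v, cent)))
      pick_by_distance(d, object$classes)
    },
    pam = {
      cent <- object$centroids[shared, , drop = FALSE]
      sd2 <- (object$sd[shared] + object$s0)^2
      d <- t(apply(x, 2L, function(v) colSums((cent - v)^2 / sd2)))
      post <- softmax_rows(-0.5 * d)
      pick_by_posterior(post, object$classes)
    },
    ccp = {
      s <- drop(crossprod(x, object$weights[shared]))
      d1 <- abs(s - object$class_means[1L]); d2 <- abs(s - object$class_means[2L])
      lab <- ifelse(s > object$threshold,
                    object$classes[which.max(object$class_means)],
                    object$classes[which.min(object$class_means)])
      lab[s == object$threshold] <- object$classes[1L]
      conf <- pmax(d1, d2) / (d1 + d2)
      conf[d1 + d2 == 0] <- 0.5
      list(label = lab, score = s, confidence = conf)
    },
    lda = {
      feats <- metagene_features(em, object$metagene_map)
      miss <- setdiff(rownames(object$means), rownames(feats))
      if (length(miss)) stop("meta-gene feature(s) not computable: ",
                             paste(miss, collapse = ", "))
      feats <- feats[rownames(object$means), , drop = FALSE]
      disc <- t(feats) %*% object$cov_inv %*% object$means -
        matrix(0.5 * colSums(object$means * (object$cov_inv %*% object$means)),
               ncol(feats), length(object$classes), byrow = TRUE)
      post <- softmax_rows(disc)
      pick_by_posterior(post, object$classes)
    },
    knn = {
      tr <- object$train[shared, , drop = FALSE]
      lab <- character(ncol(x)); conf <- numeric(ncol(x)); sc <- numeric(ncol(x))
      for (j in seq_len(ncol(x))) {
        d <- sqrt(colSums((tr - x[, j])^2))
        nn <- order(d)[seq_len(object$k)]
        votes <- table(object$train_labels[nn])
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1L) {
          agg <- vapply(top, function(l)
            sum(d[nn][object$train_labels[nn] == l]), 0)
          top <- top[agg == min(agg)]
        }
        lab[j] <- if (length(top) == 1L) top else NA_character_
        conf[j] <- max(votes) / object$k
        sc[j] <- min(d)
      }
      list(label = lab, score = sc, confidence = conf)
    },
    svm = {
      s <- drop(crossprod(x, object$w[shared])) + object$b
      lab <- ifelse(s > 0, object$positive, object$negative)
      lab[s == 0] <- NA_character_
      list(label = lab, score = s, confidence = 1 / (1 + exp(-abs(s))))
    },
    stop("unknown engine: ", object$engine))

  lab <- res$label
  lab[!is.na(res$confidence) & res$confidence < floor] <- NA_character_
  subtype_calls(samples, object$name, lab, score = res$score,
                confidence = res$confidence)
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

pick_by_distance <- function(d, classes) {
  lab <- apply(d, 1L, function(v) {
    top <- which(v == min(v))
    if (length(top) > 1L) NA_character_ else classes[top]
  })
  inv <- 1 / pmax(d, .Machine$double.eps)
  conf <- apply(inv / rowSums(inv), 1L, max)
  list(label = lab, score = apply(d, 1L, min), confidence = conf)
}

pick_by_posterior <- function(post, classes) {
  lab <- apply(post, 1L, function(v) {
    top <- which(v == max(v))
    if (length(top) > 1L) NA_character_ else classes[top]
  })
  list(label = lab, score = apply(post, 1L, max),
       confidence = apply(post, 1L, max))
}

# ---- plain-text model serialization ----

#' Serialize / deserialize trained models as structured text
#'
#' Models are written as YAML (engine kind, class labels, gene list,
#' centroid or weight tables, engine parameters) so a trained classifier
#' can be shipped and reloaded without binary artifacts. Reloading
#' reconstructs a `crc_model` whose predictions agree with the original.
#'
#' @param model A `crc_model`.
#' @param path Output/input file path.
#' @return `write_model()`: the path, invisibly; `read_model()`: a
#'   `crc_model`.
#' @export
write_model <- function(model, path) {
  x <- unclass(model)
  for (nm in names(x)) {
    if (is.matrix(x[[nm]]))
      x[[nm]] <- list(.matrix = TRUE, rows = rownames(x[[nm]]),
                      cols = colnames(x[[nm]]),
                      data = apply(x[[nm]], 2L, as.numeric, simplify = FALSE))
    else if (is.table(x[[nm]]) ||
             (is.atomic(x[[nm]]) && !is.null(names(x[[nm]]))))
      x[[nm]] <- as.list(x[[nm]])
  }
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v) && isTRUE(v$.matrix)) {
      m <- do.call(cbind, lapply(v$data, as.numeric))
      dimnames(m) <- list(unlist(v$rows), unlist(v$cols))
      x[[nm]] <- m
    } else if (is.list(v) && length(v) && all(vapply(v, is.numeric, TRUE)) &&
               !is.null(names(v))) {
      x[[nm]] <- unlist(v)
    } else if (is.list(v) && nm %in% c("genes", "classes", "train_labels")) {
      x[[nm]] <- unlist(v)
    }
  }
  if (!is.null(x$w)) x$w <- stats::setNames(as.numeric(x$w), names(x$w))
  structure(x, class = c(paste0("crc_", x$engine, "_model"), "crc_model"))
}
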