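test_that("nearest centroid stores per-class gene means", {
  em <- toy_em(matrix(c(1, 1, 1, 1,   # class A twice (point mass)
                        5, 3, 5, 3),  # class B: means 4, 4? no: per gene
                      2, 4), genes = c("gA", "gB"),
               samples = paste0("s", 1:4))
  # columns: s1,s2 class A; s3,s4 class B
  em$values[, 1:2] <- c(1, 2)
  em$values[, 3:4] <- c(5, 8)
  mod <- train_nearest_centroid(em, c("A", "A", "B", "B"))
  expect_equal(unname(mod$centroids[, "A"]), c(1, 2))
  expect_equal(unname(mod$centroids[, "B"]), c(5, 8))

  # hand-averaged centroids on non-degenerate toy data
  em2 <- toy_em(matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 2, 4, byrow = TRUE),
                genes = c("x", "y"))
  mod2 <- train_nearest_centroid(em2, c("A", "A", "B", "B"))
  expect_equal(unname(mod2$centroids[, "A"]), c(1.5, 15))
  expect_equal(unname(mod2$centroids[, "B"]), c(3.5, 35))

  expect_error(train_nearest_centroid(em2, rep("A", 4)), "at least 2 classes")
})

test_that("shrunken centroid at delta 0 equals nearest centroid in standardized space", {
  for (seed in 1:3) {
    d <- planted_two_class(n_per = 10L, n_genes = 50L, shift = 1, seed = seed)
    pam <- train_shrunken_centroid(d$em, d$labels, delta = 0)
    std <- d$em
    std$values <- std$values / (pam$sd + pam$s0)
    nc <- train_nearest_centroid(std, d$labels)
    set.seed(seed + 100)
    q <- expression_matrix(matrix(rnorm(50 * 20), 50,
                                  dimnames = list(rownames(d$em$values),
                                                  sprintf("q%02d", 1:20))))
    qs <- q; qs$values <- qs$values / (pam$sd + pam$s0)
    expect_identical(predict(pam, q)$label, predict(nc, qs)$label)
  }
})

test_that("large shrinkage collapses centroids and flattens posteriors", {
  d <- planted_two_class(n_per = 10L, shift = 1, seed = 4)
  pam <- train_shrunken_centroid(d$em, d$labels, delta = 1e6)
  expect_equal(pam$centroids[, 1], pam$centroids[, 2])
  p <- predict(pam, d$em)
  expect_true(all(is.na(p$label)))          # exact posterior ties
  expect_true(all(abs(p$confidence - 0.5) < 1e-12))
  expect_error(train_shrunken_centroid(d$em, d$labels, delta = -1), ">= 0")
})

test_that("well-separated classes give perfect resubstitution accuracy", {
  d <- planted_two_class(n_per = 20L, n_inf = 10L, shift = 3, seed = 5)
  pam <- train_shrunken_centroid(d$em, d$labels, delta = 1)
  expect_equal(mean(predict(pam, d$em)$label == d$labels), 1)
})

test_that("compound covariate predictor uses t-weights and the midpoint threshold", {
  # one informative gene, symmetric classes -> threshold 0 after centering
  set.seed(6)
  noise <- rnorm(10, 0, 0.2)
  vals <- matrix(c(-1 + noise[1:5], 1 + noise[6:10]), 1, 10,
                 dimnames = list("g1", paste0("s", 1:10)))
  vals <- vals - mean(vals)
  em <- expression_matrix(rbind(vals, g2 = rnorm(10, 0, 0.1)))
  em$values["g1", ] <- em$values["g1", ] - mean(em$values["g1", ])
  lab <- rep(c("A", "B"), each = 5)
  # make classes exactly symmetric around 0 on the informative gene
  em$values["g1", 6:10] <- -em$values["g1", 1:5]
  em$values["g2", ] <- 0.01 * seq_len(10)  # uninformative, near-zero t
  em$values["g2", ] <- em$values["g2", ] - mean(em$values["g2", ])
  em$values["g2", 6:10] <- -em$values["g2", 1:5]
  mod <- train_compound_covariate(em, lab)
  expect_equal(mod$threshold, 0, tolerance = 1e-10)

  # a sample exactly at the midpoint goes to the first (reference) class
  q <- expression_matrix(matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "q1")))
  expect_equal(predict(mod, q)$label, "A")

  expect_error(train_compound_covariate(planted_two_class(seed = 7)$em,
                                        rep(c("A", "B", "C"), length.out = 40)),
               "exactly 2 classes")
})

test_that("compound covariate predictor generalizes on planted data", {
  train <- planted_two_class(n_per = 25L, n_inf = 10L, shift = 2, seed = 8)
  test <- planted_two_class(n_per = 25L, n_inf = 10L, shift = 2, seed = 9)
  mod <- train_compound_covariate(train$em, train$labels)
  acc <- mean(predict(mod, test$em)$label == test$labels)
  expect_gt(acc, 0.9)
})

test_that("meta-gene discriminant averages members and recovers planted classes", {
  # meta-gene with members valued 1 and 3 -> feature 2
  em <- toy_em(matrix(c(1, 3), 2, 1), genes = c("m1", "m2"))
  feats <- crcbench:::metagene_features(em, list(MG = c("m1", "m2")))
  expect_equal(unname(feats["MG", 1]), 2)

  set.seed(10)
  n_per <- 15L
  lab <- rep(c("A", "B", "C"), each = n_per)
  m <- matrix(rnorm(30 * 3 * n_per), 30,
              dimnames = list(sprintf("g%02d", 1:30),
                              sprintf("s%02d", seq_len(3 * n_per))))
  # plant class structure in meta-gene space (genes 1-10 vs 11-20)
  m[1:10, lab == "B"] <- m[1:10, lab == "B"] + 3
  m[11:20, lab == "C"] <- m[11:20, lab == "C"] + 3
  mg <- list(MG1 = sprintf("g%02d", 1:10), MG2 = sprintf("g%02d", 11:20),
             MG3 = sprintf("g%02d", 21:30))
  mod <- train_metagene_lda(expression_matrix(m), lab, mg)
  expect_equal(mean(predict(mod, expression_matrix(m))$label == lab), 1)
})

test_that("meta-gene discriminant drops uncovered and constant features with warnings", {
  d <- planted_two_class(n_per = 10L, seed = 11)
  mg <- list(MG1 = sprintf("g%02d", 1:5), MGnone = c("absent1", "absent2"))
  expect_warning(mod <- train_metagene_lda(d$em, d$labels, mg),
                 "no covered members")
  expect_equal(rownames(mod$means), "MG1")

  m <- d$em$values
  m["g10", ] <- 5  # constant gene = constant singleton meta-gene
  mg2 <- list(MG1 = sprintf("g%02d", 1:5), MGconst = "g10")
  expect_warning(mod2 <- train_metagene_lda(expression_matrix(m), d$labels, mg2),
                 "constant meta-gene")
  expect_equal(rownames(mod2$means), "MG1")
})

test_that("prediction confidence floor and exact ties yield NA calls", {
  # 1 informative gene, centroids at 0 and 2
  em <- toy_em(matrix(c(0, 0, 2, 2, 0, 0, 2, 2), 2, 4, byrow = TRUE),
               genes = c("g1", "g2"))
  em$values[, ] <- rbind(c(-0.1, 0.1, 1.9, 2.1), c(-0.1, 0.1, 1.9, 2.1))
  mod <- train_shrunken_centroid(em, c("A", "A", "B", "B"), delta = 0)
  # equidistant query: exact posterior tie -> NA regardless of floor
  q_mid <- toy_em(matrix(c(1, 1), 2, 1), genes = c("g1", "g2"), samples = "mid")
  expect_true(is.na(predict(mod, q_mid)$label))

  # near-middle query: labeled at floor 0, suppressed at floor 0.90
  q_near <- toy_em(matrix(c(1.01, 1.01), 2, 1), genes = c("g1", "g2"),
                   samples = "near")
  p0 <- predict(mod, q_near, confidence_floor = 0)
  expect_false(is.na(p0$label))
  expect_lt(p0$confidence, 0.90)
  p9 <- predict(mod, q_near, confidence_floor = 0.90)
  expect_true(is.na(p9$label))

  # sample sitting on a centroid: that class, high confidence
  q_on <- toy_em(matrix(c(0, 0), 2, 1), genes = c("g1", "g2"), samples = "on")
  pon <- predict(mod, q_on)
  expect_equal(pon$label, "A")
})

test_that("KNN predicts by majority with the deterministic distance tie-break", {
  d <- planted_two_class(n_per = 10L, shift = 3, seed = 12)
  mod <- train_reference_model(d$em, d$labels, "knn", k = 1L)
  # query equal to a training sample returns that sample's label at k = 1
  q <- expression_matrix(d$em$values[, 3, drop = FALSE] + 0)
  colnames(q$values) <- "q1"
  q <- expression_matrix(q$values)
  expect_equal(predict(mod, q)$label, d$labels[3])

  # even k with a split vote: the label with smaller aggregate distance wins
  em <- toy_em(matrix(c(0, 6, 2.5, 10), 1, 4), genes = "g1",
               samples = c("a1", "a2", "b1", "b2"))
  mod2 <- train_reference_model(em, c("A", "A", "B", "B"), "knn", k = 2L)
  qq <- toy_em(matrix(1, 1, 1), genes = "g1", samples = "q")
  # neighbours of the query at 1 are a1 (distance 1) and b1 (distance 1.5)
  expect_equal(predict(mod2, qq)$label, "A")

  expect_error(train_reference_model(d$em, d$labels, "knn", k = 20L),
               "smaller than the number of training samples")
})

test_that("KNN agrees with an independent implementation on tie-free queries", {
  d <- planted_two_class(n_per = 15L, shift = 2, seed = 18)
  set.seed(19)
  q <- expression_matrix(matrix(rnorm(50 * 25), 50,
                                dimnames = list(rownames(d$em$values),
                                                sprintf("q%02d", 1:25))))
  mod <- train_reference_model(d$em, d$labels, "knn", k = 3L)
  ours <- predict(mod, q)$label
  ref <- as.character(class::knn(t(d$em$values), t(q$values),
                                 factor(d$labels), k = 3))
  expect_identical(ours, ref)
})

test_that("maximum-margin engine separates linearly separable data exactly", {
  d <- planted_two_class(n_per = 15L, n_inf = 10L, shift = 4, seed = 13)
  mod <- train_reference_model(d$em, d$labels, "max_margin")
  expect_equal(mean(predict(mod, d$em)$label == d$labels), 1)
  expect_error(train_reference_model(d$em, rep(c("A", "B", "C"), each = 10),
                                     "max_margin"), "exactly 2 classes")
})

test_that("predictions are invariant to sample order (property)", {
  d <- planted_two_class(n_per = 12L, shift = 2, seed = 14)
  set.seed(15)
  perm <- sample(ncol(d$em$values))
  emp <- expression_matrix(d$em$values[, perm], d$em$dataset[perm])
  for (mod in list(train_nearest_centroid(d$em, d$labels),
                   train_shrunken_centroid(d$em, d$labels, delta = 0.5),
                   train_compound_covariate(d$em, d$labels),
                   train_reference_model(d$em, d$labels, "knn", k = 3L))) {
    p1 <- predict(mod, d$em)
    p2 <- predict(mod, emp)
    expect_identical(p1$label[perm], p2$label, info = mod$engine)
  }
})

test_that("model serialization round trip preserves predictions", {
  d <- planted_two_class(n_per = 12L, shift = 2, seed = 16)
  mg <- list(MG1 = sprintf("g%02d", 1:10), MG2 = sprintf("g%02d", 11:20))
  mods <- list(train_nearest_centroid(d$em, d$labels, metric = "correlation"),
               train_shrunken_centroid(d$em, d$labels, delta = 0.3),
               train_compound_covariate(d$em, d$labels),
               train_metagene_lda(d$em, d$labels, mg),
               train_reference_model(d$em, d$labels, "knn", k = 3L),
               train_reference_model(d$em, d$labels, "max_margin"))
  for (mod in mods) {
    tf <- tempfile(fileext = ".yaml")
    write_model(mod, tf)
    back <- read_model(tf)
    expect_equal(predict(back, d$em), predict(mod, d$em),
                 tolerance = 1e-9, info = mod$engine)
  }
})

test_that("prediction errors on an empty gene intersection", {
  d <- planted_two_class(n_per = 10L, seed = 17)
  mod <- train_nearest_centroid(d$em, d$labels)
  alien <- toy_em(matrix(rnorm(4), 2, 2), genes = c("zz1", "zz2"))
  expect_error(predict(mod, alien), "no overlap")
})
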