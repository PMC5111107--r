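sim_two_arm <- function(n_per, hr, censor = 0, seed = 1L, rate = 0.016) {
  set.seed(seed)
  t1 <- rexp(n_per, rate)
  t2 <- rexp(n_per, rate * hr)
  t_event <- c(t1, t2)
  if (censor > 0) {
    horizon <- uniroot(function(tau) mean(pmin(t_event, tau)) / tau - censor,
                       interval = c(1e-6, max(t_event) * 1e4))$root
    cens <- runif(2 * n_per, 0, horizon)
    list(time = pmin(t_event, cens), event = as.integer(t_event <= cens),
         group = rep(c("ref", "exp"), each = n_per))
  } else {
    list(time = t_event, event = rep(1L, 2 * n_per),
         group = rep(c("ref", "exp"), each = n_per))
  }
}

test_that("null two-arm cohorts give a hazard ratio near 1", {
  d <- sim_two_arm(500, hr = 1, seed = 31)
  res <- cox_two_group(d$time, d$event, factor(d$group, c("ref", "exp")))
  expect_lt(abs(log(res$hazard_ratio)), 0.15)
})

test_that("a planted hazard ratio of 2 is recovered within simulation bounds", {
  d <- sim_two_arm(500, hr = 2, censor = 0.2, seed = 32)
  res <- cox_two_group(d$time, d$event, factor(d$group, c("ref", "exp")))
  expect_gte(res$hazard_ratio, 1.7)
  expect_lte(res$hazard_ratio, 2.35)
  expect_lt(res$p_value, 0.001)
  expect_true(res$ci_low <= res$hazard_ratio && res$hazard_ratio <= res$ci_high)
})

test_that("Cox coefficient matches a grid-search partial-likelihood oracle", {
  # 4 observations, all events, distinct times: partial likelihood by hand
  time <- c(2, 5, 7, 11)
  event <- c(1, 1, 1, 1)
  z <- c(0, 1, 0, 1)
  log_pl <- function(beta) {
    ord <- order(time)
    s <- 0
    for (i in ord) {
      risk <- time >= time[i]
      s <- s + beta * z[i] - log(sum(exp(beta * z[risk])))
    }
    s
  }
  grid <- seq(-5, 5, by = 1e-4)
  beta_hat <- grid[which.max(vapply(grid, log_pl, 0))]
  res <- cox_two_group(time, event, factor(z))
  expect_equal(res$coef, beta_hat, tolerance = 1e-3)
})

test_that("hazard ratios invert exactly and are time-scale invariant (properties)", {
  d <- sim_two_arm(100, hr = 2, censor = 0.2, seed = 33)
  g <- factor(d$group, c("ref", "exp"))
  ab <- cox_two_group(d$time, d$event, g)
  ba <- cox_two_group(d$time, d$event, factor(d$group, c("exp", "ref")))
  expect_equal(ab$hazard_ratio * ba$hazard_ratio, 1, tolerance = 1e-9)

  scaled <- cox_two_group(d$time * 12, d$event, g)
  expect_equal(scaled$hazard_ratio, ab$hazard_ratio, tolerance = 1e-9)
  expect_equal(scaled$p_value, ab$p_value, tolerance = 1e-9)
})

test_that("cox_two_group rejects degenerate inputs by name", {
  expect_error(cox_two_group(c(1, 2, 3, 4), c(1, 1, 0, 0),
                             c("a", "a", "b", "b")),
               "zero events in group: b")
  expect_error(cox_two_group(c(1, Inf), c(1, 1), c("a", "b")), "non-finite")
  expect_error(cox_two_group(c(1, -2), c(1, 1), c("a", "b")), "negative")
  expect_error(cox_two_group(1:3, c(1, 1, 1), c("a", "b", "c")), "2 levels")
})

test_that("95% CI coverage of a true hazard ratio is nominal over replicates", {
  hits <- 0L
  for (r in 1:200) {
    d <- sim_two_arm(200, hr = 2, censor = 0.2, seed = 1000L + r)
    res <- cox_two_group(d$time, d$event, factor(d$group, c("ref", "exp")))
    if (res$ci_low <= 2 && 2 <= res$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.90)
  expect_lte(hits / 200, 0.99)
})

test_that("KM estimator drops 1/n per event without censoring", {
  time <- c(3, 1, 4, 2, 5)
  km <- km_logrank(c(time, time), rep(1, 10),
                   rep(c("g1", "g2"), each = 5))
  g1 <- km$curves[km$curves$group == "g1", ]
  expect_equal(g1$time, sort(time))
  expect_equal(g1$surv, 1 - seq_len(5) / 5)
})

test_that("log-rank: literally identical groups give chi-square 0, p = 1", {
  time <- rexp(200, 0.02)
  ev <- rbinom(200, 1, 0.8)
  km <- km_logrank(c(time, time), c(ev, ev), rep(c("a", "b"), each = 200))
  expect_equal(km$chisq, 0, tolerance = 1e-9)
  expect_equal(km$p_value, 1, tolerance = 1e-9)
})

test_that("log-rank statistic equals the hand-computed observed-minus-expected form", {
  # small worked dataset, no ties
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 1, 0)
  group <- c("a", "b", "a", "b", "a", "b")
  # hand computation: at each event time, expected events in group a
  o_a <- 0; e_a <- 0; v <- 0
  for (tt in time[event == 1]) {
    at_risk <- time >= tt
    n <- sum(at_risk); n_a <- sum(at_risk & group == "a")
    d <- sum(time == tt & event == 1)
    o_a <- o_a + sum(time == tt & event == 1 & group == "a")
    e_a <- e_a + d * n_a / n
    v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / max(n - 1, 1)
  }
  chisq_hand <- (o_a - e_a)^2 / v
  km <- km_logrank(time, event, group)
  expect_equal(km$chisq, chisq_hand, tolerance = 1e-9)
})

test_that("extreme-cohort selection is the identity for 2-label classifiers", {
  d <- sim_two_arm(60, hr = 3, censor = 0.1, seed = 35)
  s <- sprintf("s%03d", seq_along(d$time))
  calls <- calls_df(s, ifelse(d$group == "ref", "good", "poor"))
  clin <- clin_df(s, d$time, d$event)
  ex <- extreme_cohort_hr(calls, clin)
  direct <- cox_two_group(d$time, d$event,
                          factor(ifelse(d$group == "ref", "good", "poor"),
                                 c("good", "poor")))
  expect_equal(ex$hazard_ratio, direct$hazard_ratio, tolerance = 1e-12)
  expect_equal(ex$p_value, direct$p_value, tolerance = 1e-12)
})

test_that("extremes of a 3-label classifier are the lowest- and highest-hazard labels", {
  set.seed(36)
  n <- 900
  lab <- sample(c("L1", "L2", "L4"), n, replace = TRUE)
  rate <- c(L1 = 1, L2 = 2, L4 = 4)[lab] * 0.016
  time <- rexp(n, rate)
  s <- sprintf("s%04d", 1:n)
  ex <- extreme_cohort_hr(calls_df(s, lab), clin_df(s, time, rep(1, n)))
  rk <- attr(ex, "label_rank")
  expect_equal(names(rk)[1], "L1")
  expect_equal(names(rk)[length(rk)], "L4")
  expect_gt(ex$hazard_ratio, 2)  # true extreme contrast is 4
  # intermediate label excluded from the two-group fit
  expect_equal(sum(ex$n), sum(lab != "L2"))
})

test_that("extreme-cohort benchmark applies stage and training-set filters", {
  set.seed(37)
  n <- 200
  s <- sprintf("s%03d", 1:n)
  lab <- rep(c("good", "poor"), n / 2)
  time <- rexp(n, ifelse(lab == "poor", 0.06, 0.02))
  stage <- rep(c("I", "II", "III", "IV"), length.out = n)
  ds <- rep(c("train", "valid"), each = n / 2)
  clin <- clin_df(s, time, rep(1, n), stage = stage, dataset = ds)
  ex <- extreme_cohort_hr(calls_df(s, lab), clin, stage_filter = c("II", "III"),
                          exclude_datasets = "train")
  expect_equal(sum(ex$n), sum(stage %in% c("II", "III") & ds == "valid"))

  only_na <- calls_df(s, NA_character_)
  expect_error(extreme_cohort_hr(only_na, clin), "fewer than 2 classified labels")
})

test_that("univariate screen splits at gene medians and summarizes proportions", {
  set.seed(38)
  n <- 600
  s <- sprintf("s%04d", 1:n)
  risk <- rbinom(n, 1, 0.5)
  m <- rbind(prog = 7 + 2 * risk + rnorm(n, 0, 0.3),   # planted prognostic gene
             null1 = rnorm(n, 7), null2 = rnorm(n, 7),
             const = rep(7, n))
  colnames(m) <- s
  time <- rexp(n, 0.016 * ifelse(risk == 1, 3, 1))
  clin <- clin_df(s, time, rep(1, n))
  res <- univariate_gene_screen(expression_matrix(m), clin)
  expect_lt(res$p_value[res$gene == "prog"], 0.05)
  expect_gt(res$hazard_ratio[res$gene == "prog"], 1.5)
  expect_true(is.na(res$p_value[res$gene == "const"]))
  # constant gene excluded from the proportion denominator
  expect_equal(attr(res, "prop_p05"),
               mean(res$p_value[res$gene != "const"] < 0.05))
})

test_that("per-signature screen proportions are plain arithmetic", {
  set.seed(39)
  n <- 400
  s <- sprintf("s%04d", 1:n)
  risk <- rbinom(n, 1, 0.5)
  m <- rbind(sig1 = 7 + 2 * risk + rnorm(n, 0, 0.3),
             sig2 = 7 + 2 * risk + rnorm(n, 0, 0.3),
             sig3 = rnorm(n, 7), sig4 = rnorm(n, 7))
  colnames(m) <- s
  time <- rexp(n, 0.016 * ifelse(risk == 1, 4, 1))
  clin <- clin_df(s, time, rep(1, n))
  sig <- signature_mean("demo", c("sig1", "sig2", "sig3", "sig4"))
  sm <- screen_by_signature(expression_matrix(m), clin, list(sig))
  expect_equal(sm$n_genes_screened, 4L)
  expect_equal(sm$prop_p05, 0.5, tolerance = 0.26)  # 2 of 4 planted
})

test_that("multivariate adjustment keeps a planted classifier effect and drops null covariates", {
  set.seed(42)
  n <- 500
  s <- sprintf("s%04d", 1:n)
  risk <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.016 * ifelse(risk == 1, 3, 1))
  msi <- sample(c("MSI", "MSS"), n, TRUE, c(0.15, 0.85))
  gender <- sample(c("M", "F"), n, TRUE)
  clin <- clin_df(s, time, rep(1, n))
  clin$msi <- msi; clin$gender <- gender
  calls <- calls_df(s, ifelse(risk == 1, "poor", "good"))
  res <- multivariate_cox(calls, clin, covariates = c("msi", "gender"))
  lab_term <- res$terms[grepl("^label", res$terms$term), ]
  expect_lt(lab_term$p_value, 0.001)
  expect_gt(lab_term$hazard_ratio, 2)
  cov_terms <- res$terms[!grepl("^label", res$terms$term), ]
  expect_true(all(abs(log(cov_terms$hazard_ratio)) < 0.2))  # planted null
})

test_that("multivariate fit reports dropped rows and rejects collinear covariates", {
  set.seed(41)
  n <- 200
  s <- sprintf("s%03d", 1:n)
  risk <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.016 * ifelse(risk == 1, 3, 1))
  clin <- clin_df(s, time, rep(1, n))
  clin$msi <- sample(c("MSI", "MSS"), n, TRUE)
  clin$msi[1:10] <- NA
  calls <- calls_df(s, ifelse(risk == 1, "poor", "good"))
  expect_message(res <- multivariate_cox(calls, clin, covariates = "msi"),
                 "10 row\\(s\\)")
  expect_equal(res$n_dropped, 10L)
  expect_equal(res$n_used, 190L)

  x <- rnorm(n)
  res2 <- expect_error(
    multivariate_cox(calls, clin[, c("sample_id", "rfs_time", "rfs_event")],
                     covariates = character(0),
                     expr_covariates = list(a = setNames(x, s),
                                            b = setNames(2 * x, s))),
    "collinear covariates: a and b")

  clin$msi[1:150] <- NA
  expect_error(multivariate_cox(calls, clin, covariates = "msi"),
               "fewer than 50%")
})
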