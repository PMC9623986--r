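test_that("RECIST dichotomization counts disease control as response", {
  expect_equal(dichotomize_response("stable disease"), "responder")
  expect_equal(dichotomize_response("partial response"), "responder")
  expect_equal(dichotomize_response("complete response"), "responder")
  expect_equal(dichotomize_response("progressive disease"), "non_responder")
  expect_equal(dichotomize_response(c("PD", "SD")),
               c("non_responder", "responder"))
  expect_error(dichotomize_response("mixed response"), "unknown RECIST")
})

test_that("ROC AUC equals pairwise probability with half-credit for ties", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(roc_auc(c(1, 1), c(TRUE, FALSE)), 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both responder")
})

test_that("ROC AUC matches brute-force pair counting on random inputs", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(round(rnorm(n), 1))  # rounding forces some ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
    if (!any(duplicated(scores)))
      expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
  }
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- rnorm(60)
  labels <- runif(60) < plogis(scores)
  if (length(unique(labels)) < 2L) labels[1:2] <- c(TRUE, FALSE)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("Kaplan-Meier steps and medians follow the product-limit estimator", {
  rec <- data.frame(pfs_months = c(1, 2, 3, 4), event_observed = 1)
  km <- km_curve(rec, rep("all", 4))
  expect_equal(km$all$steps$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$all$median, 2)  # first time survival reaches one half
  # fully censored data never leave survival 1 and have no median
  cens <- data.frame(pfs_months = c(5, 6), event_observed = 0)
  kmc <- km_curve(cens, rep("all", 2))
  expect_true(all(kmc$all$steps$surv == 1))
  expect_true(is.na(kmc$all$median))
  # a single event drops the curve to zero at its time
  one <- km_curve(data.frame(pfs_months = 5, event_observed = 1), "g")
  expect_equal(one$g$steps$surv, 0)
  expect_equal(one$g$median, 5)
})

test_that("log-rank test matches the hand-computed risk-table tableau", {
  a <- data.frame(time = c(1, 2), event = 1)
  b <- data.frame(time = c(10, 11), event = 1)
  # tableau: O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9
  e_a <- 1 / 2 + 1 / 3
  v <- (2 * 2 * 1 * 3) / (16 * 3) + (1 * 2 * 1 * 2) / (9 * 2)
  expected <- (2 - e_a)^2 / v
  got <- logrank_test(a, b)
  expect_equal(got$statistic, expected, tolerance = 1e-10)
  expect_equal(got$p_value, pchisq(expected, 1, lower.tail = FALSE))
  # statistic is invariant under swapping the groups
  expect_equal(logrank_test(b, a)$statistic, got$statistic)
  # exchangeable groups give statistic 0 and p 1
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(logrank_test(data.frame(time = 1, event = 0),
                            data.frame(time = 2, event = 0)),
               "at least one event")
})

test_that("Cox coefficients match grid-search maximization of the partial likelihood", {
  time <- c(1, 3, 5, 7, 2, 9)
  event <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_ph(time, event, x)
  expect_equal(fit$coef, oracle_cox_coef(time, event, x), tolerance = 1e-4)
  expect_true(attr(fit, "converged"))
  # identical survival in both groups: hazard ratio near 1
  t2 <- rep(c(1, 2, 3, 4), 2)
  g2 <- rep(c(0, 1), each = 4)
  null_fit <- cox_ph(t2, rep(1, 8), g2)
  expect_equal(null_fit$hr, 1, tolerance = 1e-8)
  expect_error(cox_ph(t2, rep(1, 8), rep(1, 8)), "constant covariate")
})

test_that("perfect separation is flagged as non-convergence, not silent output", {
  time <- c(1, 2, 3, 10, 11, 12)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fit <- cox_ph(time, rep(1, 6), x), "did not converge")
  expect_false(attr(fit, "converged"))
})

test_that("median-split screens recover a planted hazard and skip constants", {
  set.seed(55)
  n <- 200
  feature <- rnorm(n)
  high <- feature > stats::median(feature)
  time <- rexp(n, rate = ifelse(high, 5 * 0.2, 0.2))
  records <- data.frame(pfs_months = time, event_observed = 1)
  fm <- cbind(signal = feature, flat = rep(1, n), noise = rnorm(n))
  out <- median_split_screen(fm, records)
  expect_equal(nrow(out), 3L)
  expect_true(out$skipped[out$feature == "flat"])
  sig <- out[out$feature == "signal", ]
  expect_gt(sig$hr, 1)
  expect_lt(sig$logrank_p, 1e-6)
  expect_equal(sum(!out$skipped), 2L)
  expect_true("signal" %in% attr(out, "significant")$feature)
  # ties go to the low group: high group is strictly above the median
  expect_equal(sig$n_high, sum(high))
})

test_that("permutation overlap p-values agree with exhaustive enumeration", {
  u <- list(letters[1:6], letters[1:6], letters[1:6])
  obs <- list(c("a", "b", "c"), c("a", "b", "d"), c("a", "b", "e"))
  observed <- length(Reduce(intersect, obs))  # 2
  exact <- oracle_overlap_p(lengths(obs), u, observed)
  res <- permutation_overlap_test(obs, u, n_iterations = 10000, seed = 1234)
  mc_se <- sqrt(exact * (1 - exact) / res$n_iterations)
  expect_lt(abs(res$p_value - exact), 3 * mc_se)
  expect_equal(res$p_value, res$n_at_least_as_large / res$n_iterations)
})

test_that("degenerate overlaps give p exactly 1", {
  u <- list(letters[1:5], letters[1:5], letters[1:5])
  disjoint <- list("a", "b", "c")  # observed intersection 0
  expect_equal(permutation_overlap_test(disjoint, u, 200, seed = 1)$p_value, 1)
  full <- list(letters[1:5], letters[1:5], letters[1:5])
  expect_equal(permutation_overlap_test(full, u, 200, seed = 1)$p_value, 1)
})

test_that("oversized observed sets are rejected", {
  expect_error(
    permutation_overlap_test(list(c("a", "z"), "a", "a"),
                             list(letters[1:5], letters[1:5], letters[1:5])),
    "not a subset")
})

test_that("score-card evaluation reproduces the worked-example group sizes", {
  rec <- first_line_therapy_records()
  rep_all <- evaluate_score_card(NULL, rec, subset = list(line_number = 1))
  expect_equal(rep_all$n_responders, 9L)
  expect_equal(rep_all$n_non_responders, 12L)
  bev <- evaluate_score_card(NULL, rec,
                             subset = list(line_number = 1, drug = "bevacizumab"))
  expect_equal(bev$n, 15L)
  expect_equal(bev$n_responders, 9L)
  expect_equal(bev$n_non_responders, 6L)
  expect_error(evaluate_score_card(NULL, rec, subset = list(drug = "nosuch")),
               "no therapy record")
})

test_that("records lacking scores must join to a score card", {
  rec <- first_line_therapy_records()
  rec$bes <- NULL; rec$rank <- NULL
  expect_error(evaluate_score_card(NULL, rec), "no cards")
  cards <- list(rank_drugs(c(bevacizumab = 1), "CC-2"))
  expect_error(evaluate_score_card(cards, rec), "no matching score-card")
})
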