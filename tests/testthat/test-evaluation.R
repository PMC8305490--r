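test_that("LOOCV predicts each sample from a forest that never saw it", {
  d <- separable_data(n_per_class = 4, n_genes = 8, seed = 1)
  cv <- loocv(d$x, d$y, ntree = 20, mtry = 3, seed = 99)
  expect_equal(nrow(cv$predictions), 8)
  expect_equal(sum(cv$confusion), 8)

  # protocol identity: fold i equals a manual fit on the other n-1 rows
  # with the fold's derived seed -- the held-out sample cannot leak
  for (i in c(1, 5)) {
    fit <- ksrf(d$x[-i, ], d$y[-i], ntree = 20, mtry = 3,
                seed = ksrf:::derive_seed(99, i))
    out <- predict(fit, d$x[i, , drop = FALSE], type = "both")
    expect_equal(as.character(cv$predictions$predicted[i]),
                 as.character(out$response))
    expect_equal(unname(unlist(cv$predictions[i, levels(d$y)])),
                 unname(out$prob[1, ]))
  }
})

test_that("LOOCV handles tiny cohorts and degenerate forests", {
  x <- matrix(rnorm(3 * 4), 3, 4, dimnames = list(NULL, letters[1:4]))
  y <- factor(c("p", "p", "q"))
  expect_warning(cv <- loocv(x, y, ntree = 1, mtry = 1, seed = 1),
                 "single sample")
  expect_equal(nrow(cv$predictions), 3)
  expect_true(all(c("accuracy", "per_class", "confusion") %in% names(cv)))
  expect_true(is.finite(cv$accuracy))
})

test_that("metric formulas reproduce hand-computed confusion arithmetic", {
  # one-vs-rest 2x2: 5 of 10 true positives recovered
  cm <- matrix(c(5, 0, 5, 17), 2, 2,
               dimnames = list(c("BAV", "rest"), c("BAV", "rest")))
  m <- classification_metrics(cm)
  expect_equal(unname(m$sensitivity["BAV"]), 0.5)
  expect_equal(sprintf("%.2f%%", 100 * unname(m$sensitivity["BAV"])), "50.00%")

  # 25 of 27 correct on a 3x3 table
  cm3 <- matrix(0, 3, 3, dimnames = rep(list(c("BAV", "TAV", "control")), 2))
  diag(cm3) <- c(9, 8, 8)
  cm3["BAV", "TAV"] <- 1
  cm3["TAV", "BAV"] <- 1
  m3 <- classification_metrics(cm3)
  expect_equal(sprintf("%.2f%%", 100 * m3$accuracy), "92.59%")
  expect_equal(unname(m3$tp + m3$fn), unname(rowSums(cm3)))
  expect_equal(m3$accuracy, sum(diag(cm3)) / sum(cm3))

  # perfect classifier: all rates one
  mperf <- classification_metrics(diag(c(4, 5)))
  expect_equal(mperf$accuracy, 1)
  expect_equal(unname(mperf$sensitivity), c(1, 1))
  expect_equal(unname(mperf$specificity), c(1, 1))

  # undefined ratios surface as NaN with a warning, never silently 0
  empty <- matrix(c(2, 1, 0, 0), 2, 2, byrow = TRUE,
                  dimnames = rep(list(c("x", "y")), 2))
  expect_warning(
    expect_warning(me <- classification_metrics(empty),
                   "sensitivity undefined"),
    "specificity undefined")
  expect_true(is.nan(unname(me$sensitivity["y"])))
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
})

test_that("one-vs-rest AUC is the Mann-Whitney pair statistic", {
  expect_equal(auc_ovr(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), "p"), 1)
  expect_equal(auc_ovr(rep(0.5, 6), rep(c("p", "n"), 3), "p"), 0.5)
  # 3 concordant of 4 pairs
  expect_equal(auc_ovr(c(0.9, 0.4, 0.5, 0.1),
                       c("p", "p", "n", "n"), "p"), 0.75)
  expect_error(auc_ovr(1:3, rep("p", 3), "p"), "positive and one negative")

  # pair-counting oracle + pROC cross-check on random instances
  pair_auc <- function(s, lab, pos) {
    ps <- s[lab == pos]; ns <- s[lab != pos]
    mean(outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(14)
  for (r in 1:20) {
    n <- sample(5:20, 1)
    lab <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab <- c("p", "n", lab[-(1:2)])
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_ovr(s, lab, "p"), pair_auc(s, lab, "p"))
    expect_equal(auc_ovr(s, lab, "p"),
                 as.numeric(suppressMessages(
                   pROC::auc(pROC::roc(lab == "p", s, quiet = TRUE,
                                       direction = "<")))))
  }
})

test_that("parameter sweep aggregates cells reproducibly and order-free", {
  d <- separable_data(n_per_class = 4, n_genes = 10, seed = 2)
  sw1 <- parameter_sweep(d$x, d$y, ntree_grid = 10, mtry_grid = 3, seed = 5)
  expect_equal(nrow(sw1$grid), 1)
  expect_equal(sw1$mean, sw1$grid$accuracy)
  expect_equal(sw1$sd, 0)

  sw <- parameter_sweep(d$x, d$y, ntree_grid = c(10, 20), mtry_grid = c(2, 5),
                        seed = 5)
  swp <- parameter_sweep(d$x, d$y, ntree_grid = c(20, 10), mtry_grid = c(5, 2),
                         seed = 5)
  key <- function(g) g[order(g$ntree, g$mtry), ]
  expect_equal(key(sw$grid), key(swp$grid), ignore_attr = TRUE)

  # invalid cells fail before any fitting
  expect_error(parameter_sweep(d$x, d$y, ntree_grid = 10,
                               mtry_grid = ncol(d$x) + 1), "mtry")
})

test_that("per-gene ANOVA matches classical formulas", {
  # two groups (1,2) vs (3,4): SSB = 4, SSW = 1, df = (1, 2) -> F = 8
  x <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "g"))
  y <- factor(c("a", "a", "b", "b"))
  res <- anova_per_gene(x, y)
  expect_equal(res$statistic, 8, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pf(8, 1, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.1056)

  # F = t^2 identity on random two-group instances
  set.seed(21)
  for (r in 1:10) {
    v <- rnorm(12)
    grp <- factor(rep(c("a", "b"), 6))
    f <- anova_per_gene(matrix(v, ncol = 1), grp)$statistic
    t2 <- unname(stats::t.test(v ~ grp, var.equal = TRUE)$statistic)^2
    expect_equal(f, t2, tolerance = 1e-10)
  }

  # null behaviour: identical group means, large n -> F near 1, p far from 0
  set.seed(22)
  xn <- matrix(rnorm(300), ncol = 1)
  yn <- factor(rep(c("a", "b", "c"), each = 100))
  rn <- anova_per_gene(xn, yn)
  expect_gt(rn$p_value, 0.01)

  # zero within-group variance is flagged without a p-value
  xz <- matrix(rep(c(1, 2), each = 3), ncol = 1)
  yz <- factor(rep(c("a", "b"), each = 3))
  rz <- anova_per_gene(xz, yz)
  expect_equal(rz$flag, "zero_within_variance")
  expect_true(is.na(rz$p_value))

  # a planted shift is detected
  set.seed(23)
  xs <- matrix(rnorm(27 * 3), 27, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  ys <- factor(rep(c("a", "b", "c"), each = 9))
  xs[ys == "c", 1] <- xs[ys == "c", 1] + 5
  rs <- anova_per_gene(xs, ys, adjust = "BH")
  expect_lt(rs$p_value[1], 0.001)
  expect_true(all(rs$p_adjusted >= rs$p_value - 1e-15))
})

test_that("per-class report wires sensitivity, specificity and AUC together", {
  d <- separable_data(n_per_class = 6, n_genes = 12, gap = 8, seed = 4)
  cv <- loocv(d$x, d$y, ntree = 40, mtry = 4, seed = 3)
  expect_equal(cv$per_class$class, levels(d$y))
  expect_true(all(cv$per_class$sensitivity >= 0 & cv$per_class$sensitivity <= 1))
  expect_true(all(cv$per_class$auc >= 0 & cv$per_class$auc <= 1))
  # easily separable data: near-ceiling performance
  expect_gte(cv$accuracy, 0.9)
  expect_gte(min(cv$per_class$auc), 0.9)
})
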