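test_that("candidate draws follow the weighted-sampling law", {
  w <- c(a = 0.9, b = 0.1)
  # exhaustive draw returns every gene regardless of weights
  expect_setequal(draw_candidates(w, 2, seed = 1), c("a", "b"))
  # zero-weight genes are never drawn when enough positive ones exist
  w3 <- c(a = 0.5, b = 0, c = 0.5)
  draws <- vapply(1:500, function(s) {
    "b" %in% draw_candidates(w3, 2, seed = s)
  }, logical(1))
  expect_false(any(draws))
  expect_error(draw_candidates(w3, 3, seed = 1), "positive weight")

  # first-draw marginal matches the weights (chi-square GOF)
  first <- vapply(1:10000, function(s) draw_candidates(w, 1, seed = s),
                  character(1))
  tab <- table(factor(first, levels = names(w)))
  expect_equal(unname(tab["a"]) / 10000, 0.9, tolerance = 0.02)
  expect_gt(stats::chisq.test(tab, p = w)$p.value, 0.001)
})

test_that("best_split finds midpoint thresholds and degenerate nodes return NULL", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "g"))
  s <- best_split(x, c(0, 0, 1, 1), "g")
  expect_equal(s$gene, "g")
  expect_equal(s$threshold, 2.5)
  # perfect separation removes all impurity mass: 4 * Gini(1/2) = 2
  expect_equal(s$improvement, 2)

  # pure node: nothing to gain
  expect_null(best_split(matrix(1:3, ncol = 1), c(1, 1, 1), 1))
  # constant candidate values: no threshold separates
  expect_null(best_split(matrix(5, 4, 1), c(0, 1, 0, 1), 1))
})

test_that("a heavily weighted separating gene yields perfect training accuracy", {
  d <- separable_data(n_per_class = 10, n_genes = 50, seed = 2)
  w <- selection_weights(
    stats::setNames(c(0.99, rep(0.01 / 49, 49)), colnames(d$x)), colnames(d$x))
  fit <- ksrf(d$x, d$y, weights = w, mtry = 1, ntree = 51, seed = 4)
  expect_equal(as.character(predict(fit, d$x)), as.character(d$y))
})

test_that("fits are deterministic and uniform weights reproduce the NULL path", {
  d <- separable_data(seed = 3)
  f1 <- ksrf(d$x, d$y, ntree = 30, seed = 11)
  f2 <- ksrf(d$x, d$y, ntree = 30, seed = 11)
  expect_identical(predict(f1, d$x, type = "prob"),
                   predict(f2, d$x, type = "prob"))
  expect_identical(f1$selection_counts, f2$selection_counts)

  # an explicit all-equal weight vector is the conventional forest exactly
  f3 <- ksrf(d$x, d$y, weights = uniform_weights(colnames(d$x)),
             ntree = 30, seed = 11)
  expect_identical(predict(f1, d$x, type = "prob"),
                   predict(f3, d$x, type = "prob"))
})

test_that("prediction aggregates tree votes into fractions and labels", {
  d <- separable_data(seed = 5)
  fit <- ksrf(d$x, d$y, ntree = 7, seed = 9)
  prob <- predict(fit, d$x, type = "prob")
  expect_true(all(abs(rowSums(prob) - 1) < 1e-12))
  expect_true(all(prob >= 0 & prob <= 1))
  lab <- predict(fit, d$x)
  expect_equal(as.character(lab),
               colnames(prob)[apply(prob, 1, which.max)])

  # a single-tree forest predicts that tree's leaf class
  stump <- ksrf(d$x, d$y, ntree = 1, seed = 9)
  p1 <- predict(stump, d$x, type = "prob")
  expect_true(all(p1 %in% c(0, 1)))

  # gene mismatch is reported by name
  bad <- d$x
  colnames(bad)[2] <- "renamed"
  expect_error(predict(fit, bad), "renamed")
})

test_that("selection counts account for every internal node", {
  d <- separable_data(n_per_class = 8, n_genes = 10, gap = 10, seed = 6)
  # weight mass on the separating gene makes every tree a stump on it
  w <- selection_weights(
    stats::setNames(c(1, rep(1e-9, 9)), colnames(d$x)), colnames(d$x))
  fit <- ksrf(d$x, d$y, weights = w, mtry = 1, ntree = 25, seed = 2)
  ff <- feature_frequency(fit, 1)
  expect_equal(ff$gene, colnames(d$x)[1])
  expect_equal(ff$count, 25)
  expect_equal(fit$n_internal, 25)

  fit2 <- ksrf(d$x, d$y, ntree = 40, seed = 3)
  expect_equal(sum(feature_frequency(fit2)$count), fit2$n_internal)
  # ranks are 1..p and counts are sorted
  ff2 <- feature_frequency(fit2)
  expect_equal(ff2$rank, seq_len(ncol(d$x)))
  expect_true(all(diff(ff2$count) <= 0))
})

test_that("bootstrap bags hold n rows with the expected unique fraction", {
  set.seed(8)
  n <- 500
  x <- matrix(rnorm(n * 5), n, 5)
  y <- factor(rep(c("a", "b"), length.out = n))
  fit <- ksrf(x, y, ntree = 30, mtry = 2, min_node_size = 50, seed = 12)
  expect_equal(mean(fit$bag_unique) / n, 1 - exp(-1), tolerance = 0.05)
})

test_that("degenerate inputs are rejected", {
  d <- separable_data()
  expect_error(ksrf(d$x, rep("one", nrow(d$x))), "single class")
  expect_error(ksrf(d$x, d$y, mtry = ncol(d$x) + 1), "mtry")
  w0 <- stats::setNames(c(1, rep(0, ncol(d$x) - 1)), colnames(d$x))
  expect_error(ksrf(d$x, d$y, weights = w0, mtry = 2), "positive weight")
  expect_error(ksrf(d$x[, 1:3], d$y, weights = c(a = 1, b = 1, c = 1)),
               "do not match")
})

test_that("formula interface matches the matrix interface", {
  d <- separable_data(n_per_class = 6, n_genes = 5)
  df <- data.frame(class = d$y, d$x)
  f1 <- ksrf(class ~ ., data = df, ntree = 20, seed = 5)
  f2 <- ksrf(d$x, d$y, ntree = 20, seed = 5)
  expect_equal(unname(f1$selection_counts), unname(f2$selection_counts))
})

test_that("uniform-mode accuracy is comparable to an established forest", {
  d <- separable_data(n_per_class = 12, n_genes = 30, gap = 4, seed = 10)
  mine <- ksrf(d$x, d$y, ntree = 100, seed = 1)
  acc_mine <- mean(predict(mine, d$x) == d$y)
  rf <- ranger::ranger(y = d$y, x = as.data.frame(d$x), num.trees = 100,
                       seed = 1)
  acc_ranger <- 1 - rf$prediction.error  # OOB, a lower bound on train fit
  expect_gte(acc_mine, 0.95)
  expect_gte(acc_ranger, 0.9)
})
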