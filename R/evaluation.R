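#' Leave-one-out cross-validation of a slanted forest
#'
#' Runs the small-sample evaluation protocol: for each of the \eqn{n}
#' samples, a forest is fitted on the other \eqn{n - 1} and the held-out
#' sample is predicted; the \eqn{n} held-out predictions are assembled into
#' a confusion matrix, overall accuracy, per-class one-vs-rest sensitivity,
#' specificity and rank-based AUC on the vote fractions.
#'
#' Each fold gets its own deterministic seed derived from \code{seed} and
#' the fold index, so the report is reproducible and folds are independent
#' of evaluation order.
#'
#' @inheritParams ksrf.default
#' @param seed integer master seed for the per-fold forest seeds.
#' @param ... further arguments passed to [ksrf()] (e.g.
#'   \code{min_node_size}, \code{split_rule}).
#' @return An object of class \code{ksrf_cv}: list with \code{predictions}
#'   (data frame: sample, true, predicted, one vote-fraction column per
#'   class), \code{confusion} (k x k table, true in rows), \code{accuracy},
#'   \code{per_class} (data frame: class, sensitivity, specificity, auc),
#'   and the configuration.
#' @seealso [classification_metrics()], [auc_ovr()], [parameter_sweep()]
#' @export
loocv <- function(x, y, weights = NULL, ntree = 500, mtry = NULL, seed = 1,
                  ...) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples for LOOCV")
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  y <- droplevels(y)
  tab <- table(y)
  if (any(tab < 2))
    warning("class(es) with a single sample cannot be learned when held out: ",
            paste(names(tab)[tab < 2], collapse = ", "))
  classes <- levels(y)
  prob <- matrix(NA_real_, n, length(classes),
                 dimnames = list(rownames(x), classes))
  pred <- character(n)
  for (i in seq_len(n)) {
    y_train <- droplevels(y[-i])
    if (nlevels(y_train) < 2) {
      # the held-out sample was the only one of its class: the training
      # fold is single-class and trivially predicts that class
      only <- levels(y_train)
      prob[i, ] <- as.numeric(classes == only)
      pred[i] <- only
      next
    }
    fit <- ksrf(x[-i, , drop = FALSE], y[-i], weights = weights,
                ntree = ntree, mtry = mtry,
                seed = derive_seed(seed, i), ...)
    out <- predict(fit, x[i, , drop = FALSE], type = "both")
    # held-out classes absent from this fold's training get vote fraction 0
    prob[i, ] <- out$prob[1, match(classes, fit$classes)]
    prob[i, is.na(prob[i, ])] <- 0
    pred[i] <- as.character(out$response)
  }
  pred <- factor(pred, levels = classes)
  report <- eval_report(y, pred, prob, classes)
  report$config <- list(ntree = ntree, mtry = mtry, seed = seed,
                        weights_provenance =
                          if (is.null(weights)) "uniform"
                          else attr(weights, "provenance") %||% "user")
  report
}

derive_seed <- function(master, idx) {
  # exact in doubles: master < 2^31, so master * 7919 + idx * 104729 < 2^53
  as.integer((as.double(master) * 7919 + as.double(idx) * 104729) %% 2147483647) + 1L
}

eval_report <- function(true, pred, prob, classes) {
  cm <- confusion_matrix(true, pred, classes)
  met <- classification_metrics(cm)
  auc <- vapply(classes, function(cl) {
    if (sum(true == cl) == 0 || sum(true != cl) == 0) return(NA_real_)
    auc_ovr(prob[, cl], true, cl)
  }, numeric(1))
  per_class <- data.frame(class = classes,
                          sensitivity = met$sensitivity,
                          specificity = met$specificity,
                          auc = auc, row.names = NULL,
                          stringsAsFactors = FALSE)
  predictions <- data.frame(sample = rownames(prob) %||% seq_along(true),
                            true = true, predicted = pred,
                            stringsAsFactors = FALSE)
  predictions <- cbind(predictions, as.data.frame(prob, row.names = NULL))
  structure(list(predictions = predictions, confusion = cm,
                 accuracy = met$accuracy, per_class = per_class),
            class = "ksrf_cv")
}

#' @export
print.ksrf_cv <- function(x, ...) {
  cat(sprintf("LOOCV report: %d samples, accuracy %.2f%%\n",
              nrow(x$predictions), 100 * x$accuracy))
  print(x$confusion)
  df <- x$per_class
  df$sensitivity <- sprintf("%.2f%%", 100 * df$sensitivity)
  df$specificity <- sprintf("%.2f%%", 100 * df$specificity)
  df$auc <- sprintf("%.3f", df$auc)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Class-by-class confusion matrix
#'
#' @param true,pred factors (or vectors coercible to factor) of true and
#'   predicted labels.
#' @param classes optional class order; defaults to the union of levels.
#' @return a k x k table, true classes in rows, predictions in columns.
#' @export
confusion_matrix <- function(true, pred, classes = NULL) {
  if (is.null(classes)) classes <- union(levels(factor(true)), levels(factor(pred)))
  true <- factor(true, levels = classes)
  pred <- factor(pred, levels = classes)
  if (anyNA(true) || anyNA(pred)) stop("labels outside the class set")
  table(true = true, predicted = pred)
}

#' Accuracy and per-class sensitivity/specificity from a confusion matrix
#'
#' One-vs-rest view of a k x k confusion matrix: for class \eqn{c},
#' \eqn{TP} are correct predictions of \eqn{c}, \eqn{TN} correct
#' predictions of any other class, and
#' \deqn{Accuracy = (TP + TN) / (TP + FN + TN + FP),\quad
#'       Sensitivity = TP / (TP + FN),\quad
#'       Specificity = TN / (TN + FP).}
#' Overall accuracy is the trace over the total. A zero denominator yields
#' \code{NaN} with a warning, never a silent 0.
#'
#' @param cm a square confusion matrix/table, true classes in rows.
#' @return list with \code{accuracy}, and per-class named vectors
#'   \code{sensitivity}, \code{specificity}, \code{tp}, \code{tn},
#'   \code{fp}, \code{fn}.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("negative counts")
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  if (any(tp + fn == 0))
    warning("sensitivity undefined (no true samples) for: ",
            paste(rownames(cm)[tp + fn == 0], collapse = ", "))
  if (any(tn + fp == 0))
    warning("specificity undefined (no true negatives) for: ",
            paste(rownames(cm)[tn + fp == 0], collapse = ", "))
  list(accuracy = sum(tp) / n,
       sensitivity = sens, specificity = spec,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' One-vs-rest rank-based AUC
#'
#' Mann-Whitney estimator of the area under the ROC curve for one class
#' against the rest: the probability that a random positive sample scores
#' above a random negative one, tied pairs counting one half. Applied to
#' LOOCV vote fractions this gives the per-class AUC of the forest.
#'
#' @param scores numeric vector (e.g. vote fraction for the positive class).
#' @param labels true labels.
#' @param positive the label treated as positive.
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc_ovr <- function(scores, labels, positive) {
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("need at least one positive and one negative sample")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Sweep ntree and mtry over a LOOCV grid
#'
#' Evaluates LOOCV accuracy on every (ntree, mtry) cell of a grid and
#' summarises the grid by its mean and standard deviation. Each cell's seed
#' is derived from the master seed and the cell's parameter values, so the
#' grid is reproducible and invariant to evaluation order.
#'
#' @inheritParams loocv
#' @param ntree_grid integer vector of forest sizes; default
#'   \code{c(10, 50, 100, 250, 500, 1000)}.
#' @param mtry_grid integer vector of candidate-set sizes; default 6
#'   log-spaced values from 10 to \code{floor(ncol(x)/3)}.
#' @return An object of class \code{ksrf_sweep}: list with \code{grid}
#'   (data frame ntree, mtry, accuracy), \code{mean}, \code{sd}.
#' @export
parameter_sweep <- function(x, y, weights = NULL,
                            ntree_grid = c(10, 50, 100, 250, 500, 1000),
                            mtry_grid = NULL, seed = 1, ...) {
  x <- as.matrix(x)
  if (is.null(mtry_grid)) {
    hi <- max(10, floor(ncol(x) / 3))
    mtry_grid <- unique(round(exp(seq(log(10), log(hi), length.out = 6))))
  }
  ntree_grid <- as.integer(ntree_grid)
  mtry_grid <- as.integer(mtry_grid)
  if (length(ntree_grid) == 0 || length(mtry_grid) == 0) stop("empty grid")
  if (any(mtry_grid < 1 | mtry_grid > ncol(x)))
    stop("mtry grid values must lie in [1, ncol(x)]")
  if (any(ntree_grid < 1)) stop("ntree grid values must be positive")
  cells <- expand.grid(ntree = ntree_grid, mtry = mtry_grid)
  if (anyDuplicated(cells)) cells <- unique(cells)
  acc <- mapply(function(nt, mt) {
    cell_seed <- derive_seed(seed, nt * 131L + mt * 17L)
    loocv(x, y, weights = weights, ntree = nt, mtry = mt,
          seed = cell_seed, ...)$accuracy
  }, cells$ntree, cells$mtry)
  grid <- data.frame(ntree = cells$ntree, mtry = cells$mtry, accuracy = acc)
  structure(list(grid = grid, mean = mean(acc),
                 sd = if (nrow(grid) > 1) stats::sd(acc) else 0),
            class = "ksrf_sweep")
}

#' @export
print.ksrf_sweep <- function(x, ...) {
  cat(sprintf("LOOCV sweep over %d cells: accuracy %.1f%% +/- %.1f%%\n",
              nrow(x$grid), 100 * x$mean, 100 * x$sd))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Per-gene one-way ANOVA across classes
#'
#' Classical equal-variance one-way ANOVA of expression level on class, one
#' test per gene (via [stats::oneway.test()] with \code{var.equal = TRUE}).
#' No multiplicity adjustment is applied by default, matching the raw
#' p < 0.05 reporting convention of differential-expression summaries;
#' Benjamini-Hochberg adjustment is available via \code{adjust = "BH"}.
#' Genes with zero within-class variance are flagged and get no p-value.
#'
#' @param x numeric matrix, samples x genes.
#' @param y class labels (>= 2 classes, each with >= 2 samples).
#' @param genes optional subset of gene names/indices to test.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data frame with columns \code{gene}, \code{statistic} (F),
#'   \code{p_value}, \code{flag} (\code{""} or \code{"zero_within_variance"}),
#'   and \code{p_adjusted} when \code{adjust != "none"}.
#' @export
anova_per_gene <- function(x, y, genes = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  if (is.null(genes)) genes <- colnames(x) %||% seq_len(ncol(x))
  idx <- if (is.character(genes)) match(genes, colnames(x)) else as.integer(genes)
  if (anyNA(idx)) stop("unknown gene: ", genes[is.na(idx)][1])
  res <- lapply(idx, function(j) {
    v <- x[, j]
    if (all(tapply(v, y, stats::var) < .Machine$double.eps)) {
      return(c(NA_real_, NA_real_, 1))
    }
    ft <- stats::oneway.test(v ~ y, var.equal = TRUE)
    c(unname(ft$statistic), unname(ft$p.value), 0)
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = if (is.character(genes)) genes else
                             (colnames(x)[idx] %||% idx),
                    statistic = res[, 1], p_value = res[, 2],
                    flag = ifelse(res[, 3] == 1, "zero_within_variance", ""),
                    stringsAsFactors = FALSE)
  if (adjust != "none") out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Named forest-configuration presets
#'
#' \code{"cavs_default"} is the headline comparison configuration for the
#' aortic-valve case study (\code{ntree = 500}, \code{mtry = 500});
#' \code{"small"} is a quick-look setting.
#'
#' @param name preset name.
#' @return list with \code{ntree} and \code{mtry}.
#' @export
forest_preset <- function(name = c("cavs_default", "small")) {
  name <- match.arg(name)
  switch(name,
         cavs_default = list(ntree = 500L, mtry = 500L),
         small = list(ntree = 100L, mtry = 10L))
}
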