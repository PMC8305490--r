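#' Knowledge-slanted random forest
#'
#' Fits a classification random forest in which the \code{mtry} candidate
#' split variables at every tree node are drawn \emph{without replacement
#' with probability proportional to per-gene selection weights}, typically
#' the stationary probabilities of a random walk with restart over a
#' protein-protein interaction network seeded with disease genes (see
#' [run_rwr()] and [selection_weights()]). With uniform weights the
#' procedure is exactly the conventional random forest — the same code path
#' with equal draw probabilities.
#'
#' Each tree is grown on a bootstrap sample (size \eqn{n}, with replacement)
#' to purity or \code{min_node_size}, splitting on the candidate gene and
#' midpoint threshold that maximise the impurity decrease (Gini by default).
#' Ties in impurity decrease are broken toward the lower gene index, then
#' the lower threshold, so fits are fully deterministic given \code{seed}.
#' Prediction aggregates one vote per tree (the reached leaf's majority
#' class); vote ties are broken by class-level order.
#'
#' All randomness is driven by a per-tree stream derived from \code{seed},
#' so growing more trees never reshuffles earlier ones.
#'
#' @param x numeric matrix of expression values, samples in rows, genes in
#'   columns (column names are gene identifiers).
#' @param y class labels, one per row of \code{x}; coerced to factor. At
#'   least two classes are required.
#' @param weights a [selection_weights()] vector aligned to the columns of
#'   \code{x} (names checked when present), or \code{NULL} for uniform
#'   weights (conventional random forest).
#' @param ntree number of trees, default 500.
#' @param mtry number of candidate genes per node; default
#'   \code{floor(sqrt(ncol(x)))}. Must not exceed the number of genes with
#'   positive weight.
#' @param min_node_size nodes with at most this many samples are not split;
#'   default 1 (grow to purity).
#' @param split_rule \code{"gini"} (default) or \code{"entropy"}.
#' @param seed integer master seed; if \code{NULL}, one is drawn from R's
#'   RNG (so \code{set.seed()} upstream still gives reproducibility).
#' @param ... unused.
#' @return An object of class \code{ksrf}: list with the grown \code{trees},
#'   \code{classes}, \code{genes}, \code{selection_counts} (named per-gene
#'   split-variable usage counts whose total equals the number of internal
#'   nodes), \code{n_internal}, \code{bag_unique} (unique samples per
#'   bootstrap bag), the configuration, and \code{weights_provenance}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 30), 40, 30,
#'             dimnames = list(NULL, paste0("g", 1:30)))
#' x[1:20, 1] <- x[1:20, 1] + 3
#' y <- rep(c("case", "control"), each = 20)
#' w <- selection_weights(c(g1 = 10, g2 = 1), colnames(x))
#' fit <- ksrf(x, y, weights = w, ntree = 50, seed = 7)
#' predict(fit, x[1:3, ])
#' feature_frequency(fit, top_k = 5)
#' @seealso [predict.ksrf()], [feature_frequency()], [loocv()]
#' @export
ksrf <- function(x, ...) UseMethod("ksrf")

#' @rdname ksrf
#' @export
ksrf.default <- function(x, y, weights = NULL, ntree = 500, mtry = NULL,
                         min_node_size = 1, split_rule = c("gini", "entropy"),
                         seed = NULL, ...) {
  split_rule <- match.arg(split_rule)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be a numeric matrix (samples x genes)")
  if (anyNA(x)) stop("x contains missing values")
  p <- ncol(x)
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  y <- factor(y)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("y has a single class; nothing to classify")
  if (is.null(weights)) {
    weights <- uniform_weights(colnames(x))
  } else {
    weights <- align_weights(weights, colnames(x))
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- as.integer(mtry)
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, ncol(x)]")
  n_pos <- sum(weights > 0)
  if (mtry > n_pos)
    stop(sprintf("mtry (%d) exceeds the %d genes with positive weight", mtry, n_pos))
  if (ntree < 1) stop("ntree must be >= 1")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seed <- as.integer(seed)

  grown <- cpp_grow_forest(x, as.integer(y) - 1L, nlevels(y),
                           as.numeric(weights), as.integer(ntree), mtry,
                           as.integer(min_node_size),
                           if (split_rule == "gini") 0L else 1L,
                           as.double(seed))
  counts <- stats::setNames(grown$selection_counts, colnames(x))
  structure(list(trees = grown$trees,
                 classes = levels(y),
                 genes = colnames(x),
                 selection_counts = counts,
                 n_internal = sum(counts),
                 bag_unique = grown$bag_unique,
                 ntree = as.integer(ntree), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 split_rule = split_rule, seed = seed,
                 weights = weights,
                 weights_provenance = attr(weights, "provenance"),
                 n_samples = n,
                 call = match.call()),
            class = "ksrf")
}

#' @rdname ksrf
#' @param formula a formula such as \code{class ~ .}; every right-hand-side
#'   variable must be numeric.
#' @param data data frame holding the response and predictors.
#' @export
ksrf.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- as.matrix(mf[-1])
  fit <- ksrf.default(x, y, ...)
  fit$call <- match.call()
  fit
}

align_weights <- function(weights, genes) {
  w <- as.numeric(weights)
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), genes))
      stop("weight names do not match the expression genes (first mismatch: ",
           utils::head(c(setdiff(genes, names(weights)),
                         setdiff(names(weights), genes)), 1), ")")
    w <- as.numeric(weights[genes])
  } else if (length(w) != length(genes)) {
    stop("unnamed weights must have one entry per gene")
  }
  if (any(w < 0) || anyNA(w)) stop("weights must be non-negative and non-missing")
  if (sum(w) <= 0) stop("weights sum to zero")
  structure(stats::setNames(w / sum(w), genes),
            provenance = attr(weights, "provenance") %||% "user",
            n_missing = attr(weights, "n_missing") %||% 0L,
            class = "selection_weights")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict classes and vote fractions from a slanted forest
#'
#' @param object a fitted [ksrf()] model.
#' @param newdata numeric matrix (samples x genes). When column names are
#'   present they must match the training gene order exactly; the first
#'   mismatching gene is named in the error.
#' @param type \code{"response"} for predicted labels, \code{"prob"} for the
#'   matrix of per-class vote fractions (rows sum to 1), \code{"both"} for a
#'   list with both.
#' @param ... unused.
#' @return factor of labels, matrix of vote fractions, or a list with
#'   elements \code{response} and \code{prob}. Label ties are broken by
#'   class-level order.
#' @export
predict.ksrf <- function(object, newdata, type = c("response", "prob", "both"),
                         ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$genes))
    stop(sprintf("newdata has %d genes; the model was trained on %d",
                 ncol(newdata), length(object$genes)))
  if (!is.null(colnames(newdata))) {
    mism <- which(colnames(newdata) != object$genes)
    if (length(mism) > 0)
      stop(sprintf("gene mismatch at column %d: '%s' in newdata vs '%s' in model",
                   mism[1], colnames(newdata)[mism[1]], object$genes[mism[1]]))
  }
  votes <- cpp_predict_forest(object$trees, newdata, length(object$classes))
  prob <- votes / object$ntree
  dimnames(prob) <- list(rownames(newdata), object$classes)
  if (type == "prob") return(prob)
  lab <- factor(object$classes[apply(prob, 1, which.max)],
                levels = object$classes)
  if (type == "response") return(lab)
  list(response = lab, prob = prob)
}

#' Gene selection-frequency ranking
#'
#' Counts how many times each gene was chosen as a split variable across all
#' trees of the forest — the model's gene-ranking output. Counts sum to the
#' total number of internal nodes; ties in count are broken alphabetically.
#'
#' @param forest a fitted [ksrf()] model.
#' @param top_k number of top genes to return; default all.
#' @return data frame with columns \code{gene}, \code{count}, \code{rank},
#'   sorted by decreasing count.
#' @export
feature_frequency <- function(forest, top_k = Inf) {
  stopifnot(inherits(forest, "ksrf"))
  cnt <- forest$selection_counts
  ord <- order(-cnt, names(cnt))
  out <- data.frame(gene = names(cnt)[ord], count = as.integer(cnt[ord]),
                    rank = seq_along(cnt), stringsAsFactors = FALSE)
  utils::head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}

#' Draw candidate split variables by weighted sampling without replacement
#'
#' Exposes the candidate-draw primitive used inside [ksrf()] tree growth:
#' \code{mtry} distinct genes are drawn successively with probability
#' proportional to their remaining weight (zero-weight genes are never
#' drawn). Returned in draw order.
#'
#' @param weights a [selection_weights()] vector or non-negative numeric
#'   vector.
#' @param mtry number of genes to draw; at most the number of positive
#'   weights.
#' @param seed integer seed for the draw stream.
#' @return character vector of gene names (or integer indices if weights are
#'   unnamed), in draw order.
#' @export
draw_candidates <- function(weights, mtry, seed = 1) {
  w <- as.numeric(weights)
  if (any(w < 0)) stop("weights must be non-negative")
  if (mtry > sum(w > 0))
    stop(sprintf("mtry (%d) exceeds the %d genes with positive weight",
                 mtry, sum(w > 0)))
  idx <- cpp_draw_candidates(w, as.integer(mtry), as.double(seed))
  if (!is.null(names(weights))) names(weights)[idx] else idx
}

#' Best single split over candidate genes
#'
#' Exhaustive search over the given candidate genes for the (gene,
#' threshold) pair maximising the impurity decrease, thresholds taken at
#' midpoints between consecutive distinct sorted values. Returns \code{NULL}
#' when the node is pure or no threshold separates the rows.
#'
#' @param x numeric matrix (rows reaching the node x genes).
#' @param y class labels for the rows.
#' @param candidates gene names or column indices to search.
#' @param split_rule \code{"gini"} or \code{"entropy"}.
#' @return \code{NULL}, or a list with \code{gene}, \code{threshold} and
#'   \code{improvement} (impurity-mass decrease).
#' @export
best_split <- function(x, y, candidates, split_rule = c("gini", "entropy")) {
  split_rule <- match.arg(split_rule)
  x <- as.matrix(x)
  y <- factor(y)
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (is.character(candidates)) {
    idx <- match(candidates, colnames(x))
    if (anyNA(idx)) stop("unknown candidate gene: ", candidates[is.na(idx)][1])
  } else idx <- as.integer(candidates)
  res <- cpp_best_split(x, as.integer(y) - 1L, nlevels(y), idx,
                        if (split_rule == "gini") 0L else 1L)
  if (res$feature == 0) return(NULL)
  list(gene = if (!is.null(colnames(x))) colnames(x)[res$feature] else res$feature,
       threshold = res$threshold, improvement = res$improvement)
}

#' @export
print.ksrf <- function(x, ...) {
  cat("Knowledge-slanted random forest\n")
  cat(sprintf("  %d trees, mtry = %d, split rule = %s, weights: %s\n",
              x$ntree, x$mtry, x$split_rule, x$weights_provenance))
  cat(sprintf("  %d samples, %d genes, classes: %s\n",
              x$n_samples, length(x$genes), paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d internal nodes; top split gene: %s\n",
              x$n_internal, feature_frequency(x, 1)$gene))
  invisible(x)
}

#' @export
summary.ksrf <- function(object, top_k = 10, ...) {
  print(object)
  cat("\nTop split genes:\n")
  print(feature_frequency(object, top_k), row.names = FALSE)
  invisible(object)
}

#' Barplot of gene selection frequencies
#'
#' @param x a fitted [ksrf()] model.
#' @param top_k number of genes to show, default 20.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ksrf <- function(x, top_k = 20, ...) {
  ff <- feature_frequency(x, top_k)
  graphics::barplot(rev(ff$count), names.arg = rev(ff$gene), horiz = TRUE,
                    las = 1, xlab = sprintf("times selected in %d trees", x$ntree),
                    ...)
  invisible(ff)
}
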