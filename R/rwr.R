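#' Random walk with restart over a gene network
#'
#' Iterates the propagation recursion
#' \deqn{p^{(t+1)} = (1-\theta)\, A^\top p^{(t)} + \theta\, p^{(0)}}
#' from the seed prior \eqn{p^{(0)}} until the L1 change
#' \eqn{\lVert p^{(t+1)} - p^{(t)} \rVert_1} falls below \code{tol}, giving
#' every gene a stationary probability of being visited by a walker that
#' restarts at the disease seed genes with probability \code{theta}. Genes
#' close (in the network) to the seeds end up with high probability; these
#' values later become split-variable selection weights.
#'
#' The prior is \code{seed_p0} (default 1) on matched seed genes and
#' \code{background_p0} (default \code{1e-5}) elsewhere, used unnormalised:
#' the fixed point is linear in \eqn{p^{(0)}} and selection weights are
#' renormalised, so a normalised prior would give identical weights. Because
#' \eqn{A} is row-stochastic, the total mass \eqn{\sum_i p_i^{(t)}} is
#' invariant across iterations; the maximum drift observed is recorded in the
#' result.
#'
#' @param A a [transition_matrix()] object.
#' @param seeds character vector of seed gene identifiers. Seeds absent from
#'   the network are reported with a warning and ignored; at least one must
#'   match.
#' @param theta restart probability in \eqn{(0, 1]}; default 0.3, the value
#'   recommended for STRING protein networks. \code{theta = 1} is admitted
#'   (pure restart, \eqn{p^* = p^{(0)}}).
#' @param tol L1 convergence threshold, default \code{1e-6}.
#' @param max_iter iteration cap, default 10000. Hitting it flags
#'   \code{converged = FALSE} rather than raising an error, so weights from a
#'   slowly mixing network remain usable.
#' @param seed_p0,background_p0 prior probability for seed and non-seed
#'   genes; must satisfy \code{0 < background_p0 <= seed_p0}.
#' @return An object of class \code{rwr}: list with \code{p} (named
#'   stationary probabilities in node order), \code{p0}, \code{theta},
#'   \code{iterations}, \code{converged}, \code{residual} (final L1 change),
#'   \code{mass_drift} (max deviation of total mass), and
#'   \code{n_seeds_matched}.
#' @seealso [rwr_exact()] for the direct linear-solve fixed point,
#'   [selection_weights()] to turn the result into forest sampling weights.
#' @export
run_rwr <- function(A, seeds, theta = 0.3, tol = 1e-6, max_iter = 10000,
                    seed_p0 = 1, background_p0 = 1e-5) {
  stopifnot(inherits(A, "transition_matrix"))
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta > 1)
    stop("theta must be in (0, 1]")
  if (tol <= 0) stop("tol must be positive")
  if (!(background_p0 > 0 && background_p0 <= seed_p0))
    stop("need 0 < background_p0 <= seed_p0")
  p0 <- make_p0(A, seeds, seed_p0, background_p0)
  tA <- Matrix::t(A$A)
  p <- p0$p0
  total0 <- sum(p)
  mass_drift <- 0
  resid <- Inf
  iter <- 0L
  while (iter < max_iter) {
    p_new <- as.numeric((1 - theta) * (tA %*% p) + theta * p0$p0)
    iter <- iter + 1L
    resid <- sum(abs(p_new - p))
    mass_drift <- max(mass_drift, abs(sum(p_new) - total0))
    p <- p_new
    if (resid < tol) break
  }
  names(p) <- A$nodes
  structure(list(p = p, p0 = stats::setNames(p0$p0, A$nodes), theta = theta,
                 tol = tol, iterations = iter, converged = resid < tol,
                 residual = resid, mass_drift = mass_drift,
                 n_seeds_matched = p0$n_matched),
            class = "rwr")
}

#' Exact fixed point of the restart recursion
#'
#' Solves \eqn{(I - (1-\theta) A^\top)\, p^* = \theta\, p^{(0)}} with a dense
#' linear solve. The system is strictly diagonally dominant for
#' \eqn{\theta > 0} with a row-stochastic \eqn{A}, hence nonsingular. Intended
#' for small networks (validation, testing); use [run_rwr()] at scale.
#'
#' @inheritParams run_rwr
#' @return an object of class \code{rwr} with \code{iterations = NA} and
#'   \code{converged = TRUE}.
#' @export
rwr_exact <- function(A, seeds, theta = 0.3, seed_p0 = 1, background_p0 = 1e-5) {
  stopifnot(inherits(A, "transition_matrix"))
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta > 1)
    stop("theta must be in (0, 1]")
  p0 <- make_p0(A, seeds, seed_p0, background_p0)
  n <- length(A$nodes)
  M <- diag(n) - (1 - theta) * as.matrix(Matrix::t(A$A))
  p <- as.numeric(solve(M, theta * p0$p0))
  names(p) <- A$nodes
  structure(list(p = p, p0 = stats::setNames(p0$p0, A$nodes), theta = theta,
                 tol = NA_real_, iterations = NA_integer_, converged = TRUE,
                 residual = 0, mass_drift = 0, n_seeds_matched = p0$n_matched),
            class = "rwr")
}

make_p0 <- function(A, seeds, seed_p0, background_p0) {
  seeds <- unique(as.character(seeds))
  hit <- seeds %in% A$nodes
  if (!any(hit)) stop("no seed gene matches a network node")
  if (any(!hit))
    warning(sprintf("%d of %d seed gene(s) not in the network; ignored (e.g. %s)",
                    sum(!hit), length(seeds),
                    paste(utils::head(seeds[!hit], 3), collapse = ", ")))
  p0 <- rep(background_p0, length(A$nodes))
  p0[A$nodes %in% seeds] <- seed_p0
  list(p0 = p0, n_matched = sum(hit))
}

#' @export
print.rwr <- function(x, ...) {
  cat(sprintf("rwr: %d genes, theta = %.3g, %s after %s iteration(s), residual %.3g\n",
              length(x$p), x$theta,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              ifelse(is.na(x$iterations), "direct solve /", x$iterations),
              x$residual))
  cat(sprintf("  seeds matched: %d; top gene: %s (p = %.4g)\n",
              x$n_seeds_matched, names(x$p)[which.max(x$p)], max(x$p)))
  invisible(x)
}

#' Per-gene split-variable selection weights
#'
#' Aligns network propagation probabilities to the gene order of an
#' expression matrix and renormalises them to sum to one, giving the sampling
#' distribution used for candidate split variables in [ksrf()]. Genes present
#' in the expression data but absent from the network still need a positive
#' weight so they never silently vanish from the classifier; the
#' \code{missing_gene_policy} sets it:
#' \describe{
#'   \item{\code{"floor"} (default)}{the minimum positive entry of \code{p}
#'     — a missing gene is treated as no more relevant than the least-visited
#'     network gene.}
#'   \item{\code{"uniform_min"}}{the uniform share \code{mean(p)} — a missing
#'     gene is treated as average, which flattens the slant for genes without
#'     network evidence.}
#' }
#'
#' @param p an object of class \code{rwr}, or a named non-negative numeric
#'   vector of per-gene scores.
#' @param expression_genes character vector: gene order of the expression
#'   matrix the weights will be paired with.
#' @param missing_gene_policy \code{"floor"} or \code{"uniform_min"}.
#' @return An object of class \code{selection_weights}: a named numeric
#'   vector over \code{expression_genes}, non-negative, summing to 1, with
#'   attributes \code{provenance} (\code{"rwr"}, \code{"uniform"} or
#'   \code{"user"}) and \code{n_missing}.
#' @export
selection_weights <- function(p, expression_genes,
                              missing_gene_policy = c("floor", "uniform_min")) {
  missing_gene_policy <- match.arg(missing_gene_policy)
  provenance <- "user"
  if (inherits(p, "rwr")) {
    provenance <- "rwr"
    p <- p$p
  }
  stopifnot(is.numeric(p), !is.null(names(p)))
  if (any(p < 0)) stop("scores must be non-negative")
  expression_genes <- as.character(expression_genes)
  if (length(expression_genes) == 0) stop("expression_genes is empty")
  idx <- match(expression_genes, names(p))
  if (all(is.na(idx))) stop("no expression gene is present in the network scores")
  fill <- switch(missing_gene_policy,
                 floor = min(p[p > 0]),
                 uniform_min = mean(p))
  w <- ifelse(is.na(idx), fill, p[idx])
  if (sum(w) <= 0) stop("all selection weights are zero")
  w <- w / sum(w)
  structure(stats::setNames(w, expression_genes),
            provenance = provenance, n_missing = sum(is.na(idx)),
            class = "selection_weights")
}

#' Uniform selection weights (conventional random forest)
#'
#' @param expression_genes character vector of gene identifiers.
#' @return a \code{selection_weights} vector with equal entries and
#'   provenance \code{"uniform"}.
#' @export
uniform_weights <- function(expression_genes) {
  expression_genes <- as.character(expression_genes)
  n <- length(expression_genes)
  if (n == 0) stop("expression_genes is empty")
  structure(stats::setNames(rep(1 / n, n), expression_genes),
            provenance = "uniform", n_missing = 0L,
            class = "selection_weights")
}

#' @export
print.selection_weights <- function(x, ...) {
  cat(sprintf("selection_weights: %d genes (provenance: %s, %d filled by policy)\n",
              length(x), attr(x, "provenance"), attr(x, "n_missing")))
  top <- utils::head(sort(unclass(x), decreasing = TRUE), 5)
  cat("  top:", paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Write selection weights with a provenance sidecar
#'
#' Writes \code{gene<TAB>rwr_probability<TAB>selection_weight} and a JSON
#' sidecar (\code{<path>.json}) recording \code{theta}, \code{tol},
#' \code{iterations}, \code{converged} and \code{n_seeds_matched}.
#'
#' @param w a \code{selection_weights} vector.
#' @param path output TSV path.
#' @param rwr_result the \code{rwr} object the weights came from, or
#'   \code{NULL} for uniform/user weights.
#' @return \code{path}, invisibly.
#' @export
write_weights <- function(w, path, rwr_result = NULL) {
  stopifnot(inherits(w, "selection_weights"))
  prob <- if (!is.null(rwr_result)) {
    p <- rwr_result$p[names(w)]
    ifelse(is.na(p), 0, p)
  } else rep(NA_real_, length(w))
  utils::write.table(
    data.frame(gene = names(w), rwr_probability = prob,
               selection_weight = as.numeric(w)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(provenance = attr(w, "provenance"),
               n_genes = length(w), n_missing = attr(w, "n_missing"))
  if (!is.null(rwr_result))
    meta <- c(meta, list(theta = rwr_result$theta, tol = rwr_result$tol,
                         iterations = rwr_result$iterations,
                         converged = rwr_result$converged,
                         n_seeds_matched = rwr_result$n_seeds_matched))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read selection weights written by [write_weights()]
#'
#' @param path TSV path.
#' @return a \code{selection_weights} vector (provenance \code{"user"} unless
#'   the sidecar says otherwise).
#' @export
read_weights <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  w <- tab$selection_weight
  if (any(w < 0)) stop("negative selection weight in ", path)
  prov <- "user"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$provenance)) prov <- meta$provenance
  }
  structure(stats::setNames(w / sum(w), tab$gene),
            provenance = prov, n_missing = 0L, class = "selection_weights")
}

#' Read a seed-gene list (one identifier per line, '#' comments allowed)
#'
#' @param path file path.
#' @return character vector of gene identifiers.
#' @export
read_seed_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}
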