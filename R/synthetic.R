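#' Simulation configuration for network-guided classification benchmarks
#'
#' Describes a synthetic study emulating the structure the slanted forest is
#' designed for: a scale-free weighted gene network carrying a set of seed
#' genes near a planted informative neighbourhood, and a small multi-class
#' expression cohort in which one class (the controls) is easily separable
#' from the others while the two case classes differ only in a small
#' informative gene subset.
#'
#' Default dimensions (2000 genes, class sizes 10/9/8) keep the
#' high-dimensional p >> n regime of a small RNA-seq cohort at desk-scale
#' runtime. Effect sizes are in units of the noise standard deviation:
#' \code{easy_shift} separates the control class from both case classes on
#' every informative gene; \code{hard_shift} separates case class 1 from
#' case class 2 on only the first \code{n_hard} informative genes.
#'
#' @param n_genes number of genes (network nodes), default 2000.
#' @param n_informative number of informative genes planted as a connected
#'   network neighbourhood, default 30.
#' @param n_hard size of the informative subset that differs between the two
#'   case classes, default 10.
#' @param n_seed_genes number of seed genes handed to the random walk,
#'   default 20.
#' @param class_sizes named integer vector of per-class sample counts,
#'   default \code{c(BAV = 10, TAV = 9, control = 8)}.
#' @param easy_shift control-vs-cases mean shift (in sd units) on all
#'   informative genes, default 3.
#' @param hard_shift case1-vs-case2 mean shift on the \code{n_hard} subset,
#'   default 2.
#' @param noise_sd residual standard deviation, default 1.
#' @param attachment preferential-attachment parameter (edges added per new
#'   node), default 2.
#' @param seed_overlap fraction of seed genes drawn from the informative
#'   set, default 0.5; the rest are drawn at random from the remaining
#'   genes. \code{0} with \code{random_seeds = TRUE} gives the null control.
#' @param random_seeds if \code{TRUE}, seed genes are drawn uniformly at
#'   random disjoint from the informative set (ignores
#'   \code{seed_overlap}) — the negative control in which network knowledge
#'   carries no signal.
#' @param two_class if \code{TRUE}, the two case classes are merged into a
#'   single \code{"CAVS"} class (cases vs controls).
#' @return a list of class \code{ksrf_sim_config}.
#' @seealso [scenario_presets()], [simulate_scenario()]
#' @export
sim_config <- function(n_genes = 2000, n_informative = 30, n_hard = 10,
                       n_seed_genes = 20,
                       class_sizes = c(BAV = 10, TAV = 9, control = 8),
                       easy_shift = 3, hard_shift = 2, noise_sd = 1,
                       attachment = 2, seed_overlap = 0.5,
                       random_seeds = FALSE, two_class = FALSE) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_informative = as.integer(n_informative),
              n_hard = as.integer(n_hard),
              n_seed_genes = as.integer(n_seed_genes),
              class_sizes = class_sizes,
              easy_shift = easy_shift, hard_shift = hard_shift,
              noise_sd = noise_sd, attachment = attachment,
              seed_overlap = seed_overlap,
              random_seeds = isTRUE(random_seeds),
              two_class = isTRUE(two_class))
  validate_sim_config(cfg)
  class(cfg) <- "ksrf_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 10) stop("n_genes must be >= 10")
  if (cfg$n_informative > cfg$n_genes) stop("n_informative exceeds n_genes")
  if (cfg$n_hard > cfg$n_informative) stop("n_hard exceeds n_informative")
  if (cfg$seed_overlap < 0 || cfg$seed_overlap > 1)
    stop("seed_overlap must be in [0, 1]")
  if (any(cfg$class_sizes < 2)) stop("every class needs >= 2 samples")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  n_overlap <- round(cfg$n_seed_genes * cfg$seed_overlap)
  if (!cfg$random_seeds && n_overlap > cfg$n_informative)
    stop(sprintf("impossible overlap: %d seed genes x overlap %.2f exceeds %d informative genes",
                 cfg$n_seed_genes, cfg$seed_overlap, cfg$n_informative))
  invisible(cfg)
}

#' Named simulation presets
#'
#' \describe{
#'   \item{\code{easy_two_class}}{cases (19) vs controls (8); all informative
#'     genes shifted in controls — the easily separable regime where the
#'     conventional forest already does well.}
#'   \item{\code{hard_three_class}}{three classes 10/9/8; the two case
#'     classes differ only on the \code{n_hard} informative subset — the
#'     overlapping-class regime where network knowledge should help.}
#'   \item{\code{null_random_seeds}}{as \code{hard_three_class} but with
#'     seed genes drawn at random, disjoint from the informative set — the
#'     negative control under which the slanted forest should match the
#'     conventional one.}
#' }
#'
#' @return named list of [sim_config()] objects.
#' @export
scenario_presets <- function() {
  list(
    easy_two_class = sim_config(two_class = TRUE),
    hard_three_class = sim_config(),
    null_random_seeds = sim_config(random_seeds = TRUE)
  )
}

#' Generate a scale-free weighted gene network with planted structure
#'
#' Grows a preferential-attachment (Barabasi-Albert) graph — PPI networks
#' are heavy-tailed — and draws edge confidences from a Beta(2, 2)
#' distribution on (0, 1]. The informative genes are planted as a connected
#' neighbourhood (a breadth-first ball around a random start node), and the
#' seed genes overlap them by the configured fraction, emulating
#' literature-derived disease genes lying near the true signal in the
#' network.
#'
#' @param config a [sim_config()] object.
#' @param seed integer RNG seed.
#' @return list with \code{graph} (a [ppi_graph()]), \code{informative},
#'   \code{hard}, and \code{seed_genes} (character vectors of gene ids).
#' @export
generate_network <- function(config, seed = 1) {
  stopifnot(inherits(config, "ksrf_sim_config"))
  validate_sim_config(config)
  set.seed(as.integer(seed))
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  ig <- igraph::sample_pa(n, power = 1, m = config$attachment,
                          directed = FALSE)
  el <- igraph::as_edgelist(ig, names = FALSE)
  w <- stats::rbeta(nrow(el), 2, 2)
  w[w <= 0] <- .Machine$double.eps
  g <- ppi_graph(data.frame(from = gene_ids[el[, 1]], to = gene_ids[el[, 2]],
                            weight = w, stringsAsFactors = FALSE),
                 nodes = gene_ids)
  # informative genes: breadth-first ball (connected) around a random start
  start <- sample.int(n, 1)
  bfs_order <- as.integer(igraph::bfs(ig, root = start, order = TRUE)$order)
  informative <- gene_ids[bfs_order[seq_len(config$n_informative)]]
  hard <- informative[seq_len(config$n_hard)]
  if (config$random_seeds) {
    pool <- setdiff(gene_ids, informative)
    seed_genes <- sample(pool, config$n_seed_genes)
  } else {
    n_overlap <- round(config$n_seed_genes * config$seed_overlap)
    seed_genes <- c(sample(informative, n_overlap),
                    sample(setdiff(gene_ids, informative),
                           config$n_seed_genes - n_overlap))
  }
  list(graph = g, informative = informative, hard = hard,
       seed_genes = seed_genes)
}

#' Generate a labelled expression matrix with planted class structure
#'
#' Every gene gets a baseline mean drawn from N(0, 1); samples are the
#' baseline plus N(0, \code{noise_sd}) noise, on the normalised (Gaussian)
#' scale the classifier consumes. Control samples are shifted by
#' \code{easy_shift} on all informative genes; case-class-1 samples are
#' shifted by \code{hard_shift} on the \code{n_hard} subset. The true
#' per-gene class means are returned for checking.
#'
#' @param truth the list returned by [generate_network()] (or any list with
#'   \code{informative} and \code{hard} gene vectors and a \code{graph}).
#' @param config a [sim_config()] object.
#' @param seed integer RNG seed.
#' @return list with \code{x} (samples x genes matrix), \code{y} (factor),
#'   and \code{class_means} (genes x classes matrix).
#' @export
generate_expression <- function(truth, config, seed = 1) {
  stopifnot(inherits(config, "ksrf_sim_config"))
  set.seed(as.integer(seed))
  genes <- truth$graph$nodes
  if (!all(truth$informative %in% genes))
    stop("informative genes not all present in the graph")
  sizes <- config$class_sizes
  classes <- names(sizes)
  n <- sum(sizes)
  baseline <- stats::rnorm(length(genes))
  class_means <- matrix(baseline, length(genes), length(classes),
                        dimnames = list(genes, classes))
  ctrl <- length(classes)  # last class plays the easily separable controls
  class_means[truth$informative, ctrl] <-
    class_means[truth$informative, ctrl] + config$easy_shift * config$noise_sd
  if (length(classes) >= 3)
    class_means[truth$hard, 1] <-
      class_means[truth$hard, 1] + config$hard_shift * config$noise_sd
  y <- factor(rep(classes, sizes), levels = classes)
  x <- matrix(stats::rnorm(n * length(genes), sd = config$noise_sd),
              n, length(genes))
  x <- x + t(class_means[, as.integer(y), drop = FALSE])
  dimnames(x) <- list(sprintf("s%02d", seq_len(n)), genes)
  if (config$two_class && length(classes) >= 3) {
    merged <- ifelse(y == classes[ctrl], "control", "CAVS")
    y <- factor(merged, levels = c("CAVS", "control"))
  }
  list(x = x, y = y, class_means = class_means)
}

#' Simulate a complete synthetic study
#'
#' Runs [generate_network()] then [generate_expression()] under seeds
#' derived from one master seed and bundles network, seed genes, ground
#' truth and expression cohort into one object.
#'
#' @param config a [sim_config()], or the name of a [scenario_presets()]
#'   entry.
#' @param seed integer master seed.
#' @return An object of class \code{ksrf_sim}: list with \code{graph},
#'   \code{seed_genes}, \code{informative}, \code{hard}, \code{x}, \code{y},
#'   \code{class_means}, \code{config}, \code{seed}.
#' @examples
#' sim <- simulate_scenario(sim_config(n_genes = 200, n_informative = 10,
#'                                     n_hard = 5, n_seed_genes = 6), seed = 1)
#' table(sim$y)
#' @export
simulate_scenario <- function(config = "hard_three_class", seed = 1) {
  if (is.character(config)) {
    presets <- scenario_presets()
    if (!config %in% names(presets))
      stop("unknown preset '", config, "'; available: ",
           paste(names(presets), collapse = ", "))
    config <- presets[[config]]
  }
  stopifnot(inherits(config, "ksrf_sim_config"))
  net <- generate_network(config, seed = derive_seed(seed, 1))
  expr <- generate_expression(net, config, seed = derive_seed(seed, 2))
  structure(list(graph = net$graph, seed_genes = net$seed_genes,
                 informative = net$informative, hard = net$hard,
                 x = expr$x, y = expr$y, class_means = expr$class_means,
                 config = config, seed = as.integer(seed)),
            class = "ksrf_sim")
}

#' @export
print.ksrf_sim <- function(x, ...) {
  cat(sprintf("ksrf_sim: %d genes, %d samples (%s), %d informative (%d hard), %d seed genes%s\n",
              length(x$graph$nodes), nrow(x$x),
              paste(sprintf("%s=%d", levels(x$y), table(x$y)), collapse = ", "),
              length(x$informative), length(x$hard), length(x$seed_genes),
              if (x$config$random_seeds) " (random, null control)" else ""))
  invisible(x)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Writes the edge-list TSV, the expression TSV (genes in rows, samples in
#' columns), the sample-label TSV, the seed-gene list, and a ground-truth
#' JSON — the same formats the real pipeline reads.
#'
#' @param sim a [simulate_scenario()] object.
#' @param dir output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ksrf_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(network = file.path(dir, "network.tsv"),
             expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             seeds = file.path(dir, "seeds.txt"),
             truth = file.path(dir, "truth.json"))
  write_edge_list(sim$graph, files["network"])
  write_expression(sim$x, files["expression"])
  write_labels(sim$y, rownames(sim$x), files["labels"])
  writeLines(sim$seed_genes, files["seeds"])
  jsonlite::write_json(list(informative = sim$informative, hard = sim$hard,
                            seed_genes = sim$seed_genes,
                            config = unclass(sim$config), seed = sim$seed),
                       files["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}

#' Read/write expression matrices and label tables
#'
#' The expression TSV stores genes in rows and samples in columns with the
#' gene identifier in the first column (the usual orientation of expression
#' deliverables); it is transposed to samples x genes on read. The label TSV
#' has columns \code{sample} and \code{class}.
#'
#' @param path file path.
#' @return \code{read_expression}: numeric matrix, samples x genes.
#'   \code{read_labels}: data frame with \code{sample} and \code{class}.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- tab[[1]]
  if (anyDuplicated(genes)) stop("duplicated gene identifiers in ", path)
  m <- t(as.matrix(tab[-1]))
  colnames(m) <- genes
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  m
}

#' @rdname read_expression
#' @param x samples x genes numeric matrix.
#' @export
write_expression <- function(x, path) {
  tab <- data.frame(gene = colnames(x), t(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "class") %in% names(tab)))
    stop("label table must have columns 'sample' and 'class'")
  tab
}

#' @rdname read_expression
#' @param y class labels.
#' @param samples sample identifiers.
#' @export
write_labels <- function(y, samples, path) {
  utils::write.table(data.frame(sample = samples, class = as.character(y)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
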