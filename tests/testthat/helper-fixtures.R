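# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# graph from a compact edge spec: list of c(from, to, weight)
graph_from_rows <- function(rows, nodes = NULL) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(from = r[[1]], to = r[[2]], weight = as.numeric(r[[3]]),
               stringsAsFactors = FALSE)))
  ppi_graph(df, nodes = nodes)
}

# random connected weighted graph (preferential attachment is connected by
# construction); returns a ppi_graph
random_connected_graph <- function(n, seed, m = 2) {
  set.seed(seed)
  ig <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  el <- igraph::as_edgelist(ig, names = FALSE)
  ids <- sprintf("n%04d", seq_len(n))
  ppi_graph(data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                       weight = stats::runif(nrow(el), 0.1, 1),
                       stringsAsFactors = FALSE),
            nodes = ids)
}

# two-class expression data where gene 1 separates the classes perfectly
separable_data <- function(n_per_class = 10, n_genes = 20, gap = 6, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * n_genes), n, n_genes,
              dimnames = list(NULL, sprintf("g%03d", seq_len(n_genes))))
  x[seq_len(n_per_class), 1] <- rnorm(n_per_class) + gap
  list(x = x, y = factor(rep(c("case", "control"), each = n_per_class)))
}

# write an edge-list file from text lines, return its path
edge_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# small simulation config for fast structural tests
small_sim_config <- function(...) {
  sim_config(n_genes = 200, n_informative = 12, n_hard = 5,
             n_seed_genes = 8, ...)
}
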