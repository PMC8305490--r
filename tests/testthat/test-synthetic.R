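test_that("simulation is deterministic and structured as configured", {
  cfg <- small_sim_config()
  s1 <- simulate_scenario(cfg, seed = 7)
  s2 <- simulate_scenario(cfg, seed = 7)
  expect_identical(s1$graph$edges, s2$graph$edges)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$y, s2$y)
  expect_identical(s1$seed_genes, s2$seed_genes)

  expect_equal(length(s1$graph$nodes), cfg$n_genes)
  expect_equal(unname(table(s1$y)), unname(cfg$class_sizes), ignore_attr = TRUE)
  expect_equal(length(s1$informative), cfg$n_informative)
  expect_equal(length(s1$seed_genes), cfg$n_seed_genes)
  expect_true(all(s1$hard %in% s1$informative))
  expect_true(all(s1$informative %in% s1$graph$nodes))
  # configured overlap is honoured exactly
  expect_equal(sum(s1$seed_genes %in% s1$informative),
               round(cfg$n_seed_genes * cfg$seed_overlap))

  full <- simulate_scenario(small_sim_config(seed_overlap = 1), seed = 7)
  expect_true(all(full$seed_genes %in% full$informative))
})

test_that("informative genes form a connected network neighbourhood", {
  s <- simulate_scenario(small_sim_config(), seed = 9)
  ig <- igraph::graph_from_data_frame(s$graph$edges[1:2], directed = FALSE,
                                      vertices = s$graph$nodes)
  sub <- igraph::induced_subgraph(ig, s$informative)
  expect_true(igraph::is_connected(sub))
})

test_that("preferential attachment gives heavy-tailed degrees", {
  hits <- vapply(1:5, function(s) {
    net <- generate_network(sim_config(n_genes = 1000), seed = s)
    deg <- table(c(net$graph$edges$from, net$graph$edges$to))
    max(deg) > 10 * stats::median(deg)
  }, logical(1))
  expect_true(all(hits))
})

test_that("class means and shifts are planted as configured", {
  cfg <- small_sim_config(easy_shift = 3, hard_shift = 2)
  s <- simulate_scenario(cfg, seed = 3)
  other <- setdiff(s$graph$nodes, s$informative)
  cm <- s$class_means
  # controls shifted on every informative gene, nowhere else (TAV carries
  # no shift of its own, so it is the clean reference)
  expect_equal(cm[s$informative, "control"] - cm[s$informative, "TAV"],
               rep(3, length(s$informative)), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(cm[other, "control"], cm[other, "TAV"], tolerance = 1e-12)
  # case classes differ only on the hard subset
  soft <- setdiff(s$informative, s$hard)
  expect_equal(cm[s$hard, "BAV"] - cm[s$hard, "TAV"],
               rep(2, length(s$hard)), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(cm[soft, "BAV"], cm[soft, "TAV"], tolerance = 1e-12)

  # hard_shift = 0 makes the case classes exchangeable by construction
  s0 <- simulate_scenario(small_sim_config(hard_shift = 0), seed = 3)
  expect_equal(s0$class_means[, "BAV"], s0$class_means[, "TAV"],
               tolerance = 1e-12)
})

test_that("sample means converge to the planted class means", {
  cfg <- sim_config(n_genes = 50, n_informative = 8, n_hard = 4,
                    n_seed_genes = 5,
                    class_sizes = c(BAV = 500, TAV = 500, control = 500))
  s <- simulate_scenario(cfg, seed = 5)
  for (cl in levels(s$y)) {
    mu_hat <- colMeans(s$x[s$y == cl, ])
    expect_lt(max(abs(mu_hat - s$class_means[, cl])), 0.2 * cfg$noise_sd)
  }
})

test_that("random-seed null control decouples seeds from the signal", {
  s <- simulate_scenario("null_random_seeds", seed = 11)
  expect_true(s$config$random_seeds)
  expect_equal(length(intersect(s$seed_genes, s$informative)), 0)
})

test_that("propagation from planted seeds ranks informative genes high", {
  for (seed in c(1, 2)) {
    s <- simulate_scenario(small_sim_config(), seed = seed)
    w <- rwr_weights(s)
    rk <- rank(-as.numeric(w))
    names(rk) <- names(w)
    expect_lt(stats::median(rk[s$informative]),
              stats::median(rk[setdiff(names(w), s$informative)]))
  }
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(n_informative = 5, n_hard = 3, n_seed_genes = 20,
                          seed_overlap = 1),
               "impossible overlap")
  expect_error(sim_config(n_genes = 5), "n_genes")
  expect_error(sim_config(class_sizes = c(a = 1, b = 5)), "2 samples")
  expect_error(simulate_scenario("no_such_preset"), "available")
})

test_that("a written study round-trips through the pipeline readers", {
  s <- simulate_scenario(small_sim_config(), seed = 13)
  dir <- withr::local_tempdir()
  files <- write_simulation(s, dir)
  expect_true(all(file.exists(files)))

  x2 <- read_expression(files["expression"])
  expect_equal(x2, s$x, tolerance = 1e-12)
  lab <- read_labels(files["labels"])
  expect_equal(lab$class, as.character(s$y))
  expect_equal(read_seed_list(files["seeds"]), s$seed_genes)
  g2 <- read_edge_list(files["network"], score_scale = "unit")
  expect_setequal(g2$nodes, s$graph$nodes)  # PA graphs have no isolated nodes
  expect_equal(sort(g2$edges$weight), sort(s$graph$edges$weight),
               tolerance = 1e-12)
  truth <- jsonlite::read_json(files["truth"], simplifyVector = TRUE)
  expect_equal(truth$informative, s$informative)
  expect_equal(truth$hard, s$hard)
})
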