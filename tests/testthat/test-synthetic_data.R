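small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 60, n_samples = 80, n_genesets = 8,
         geneset_size_range = c(6, 12), n_drivers_per_subtype = 5),
    list(...))
  do.call(synthetic_config, args)
}

test_that("preferential attachment yields the ledgered edge count", {
  # minimum size: complete graph on m + 1 nodes
  tiny <- generate_network(4, 3, seed = 1)
  expect_length(tiny$nodes, 4L)
  expect_equal(nrow(tiny$edges), choose(4, 2))

  net <- generate_network(200, 3, seed = 7)
  expect_length(net$nodes, 200L)
  expect_equal(nrow(net$edges), choose(4, 2) + 3 * (200 - 4))  # 594
  expect_true(all(net$edges$weight >= 700 & net$edges$weight <= 1000))

  # byte-identical under the same seed
  expect_identical(net$edges, generate_network(200, 3, seed = 7)$edges)
  expect_false(identical(net$edges, generate_network(200, 3, seed = 8)$edges))

  # connected, with a heavy-tailed degree distribution (hubs emerge)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_gt(max(igraph::degree(g)), 3 * 3)

  expect_error(generate_network(3, 3), "attachment_edges")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(driver_mutation_rate = 0.01,
                                background_mutation_rate = 0.02), "exceed")
  expect_error(synthetic_config(geneset_size_range = c(10, 1000)),
               "geneset_size_range")
  expect_error(synthetic_config(background_mutation_rate = 0), "rates")
  expect_error(synthetic_config(censoring_rate = -1), "positive")
})

test_that("degenerate rates mutate exactly the driver module", {
  cfg <- synthetic_config(n_genes = 40, n_samples = 20, n_subtypes = 1,
                          n_genesets = 4, geneset_size_range = c(5, 8),
                          n_drivers_per_subtype = 4,
                          background_mutation_rate = 1e-9,
                          driver_mutation_rate = 1, seed = 3)
  co <- generate_cohort(cfg)
  drivers <- sort(co$drivers[[1]])
  for (i in seq_len(nrow(co$mutations))) {
    expect_identical(sort(colnames(co$mutations)[co$mutations[i, ] > 0]),
                     drivers)
  }
})

test_that("cohorts are reproducible and structurally consistent", {
  cfg <- small_config(seed = 11)
  co <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co$mutations, co2$mutations)
  expect_identical(co$survival, co2$survival)
  expect_identical(co$genesets, co2$genesets)

  expect_equal(sort(unique(unname(co$true_labels))), 1:2)
  expect_identical(rownames(co$mutations), co$survival$sample_id)
  expect_identical(colnames(co$mutations), co$network$nodes)
  expect_true(all(rowSums(co$mutations) > 0))  # resampling guarantee
  all_set_genes <- unique(unlist(co$genesets))
  for (d in co$drivers) expect_true(all(d %in% all_set_genes))
  expect_true(all(co$survival$time > 0))
  expect_true(all(co$survival$event %in% 0:1))
})

test_that("non-driver mutation frequency matches the background rate", {
  cfg <- small_config(seed = 21, n_samples = 200)
  co <- generate_cohort(cfg)
  non_drivers <- setdiff(colnames(co$mutations), unlist(co$drivers))
  obs <- mean(co$mutations[, non_drivers])
  p <- cfg$background_mutation_rate
  n_trials <- nrow(co$mutations) * length(non_drivers)
  # zero-mutation resampling nudges the rate up very slightly; 3 SD band
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n_trials) + 1e-4)
})

test_that("planted hazard ratio is recovered by the exponential MLE", {
  cfg <- synthetic_config(n_samples = 500, n_genes = 60, n_genesets = 8,
                          geneset_size_range = c(6, 12),
                          n_drivers_per_subtype = 5,
                          subtype_hazard_ratio = 3,
                          censoring_rate = 1e-6, seed = 5)
  co <- generate_cohort(cfg)
  g2 <- co$true_labels == 2
  hr_hat <- exp_mle_hazard(co$survival$time[g2], co$survival$event[g2]) /
    exp_mle_hazard(co$survival$time[!g2], co$survival$event[!g2])
  expect_lt(abs(hr_hat - 3) / 3, 0.2)
})

test_that("with no planted hazard the log-rank test keeps its 5% size", {
  cfg <- small_config(subtype_hazard_ratio = 1, n_samples = 120)
  rejections <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    co <- generate_cohort(small_config(subtype_hazard_ratio = 1,
                                       n_samples = 120, seed = 1000 + i))
    p <- logrank_test(co$survival, co$true_labels)$p_value
    rejections <- rejections + (p < 0.05)
  }
  rate <- rejections / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("generation fails loudly when rates cannot mutate a sample", {
  cfg <- synthetic_config(n_genes = 10, n_samples = 5, n_subtypes = 1,
                          n_genesets = 2, geneset_size_range = c(2, 3),
                          n_drivers_per_subtype = 1,
                          background_mutation_rate = 1e-9,
                          driver_mutation_rate = 2e-9, seed = 1)
  expect_error(generate_cohort(cfg), "background_mutation_rate")
})

test_that("cohorts round-trip through the standard text formats", {
  co <- generate_cohort(small_config(seed = 31))
  outdir <- withr::local_tempdir()
  paths <- write_cohort(co, outdir)
  expect_true(all(file.exists(paths)))

  m <- read_mutation_matrix(paths[["mutations"]])
  kept <- colnames(co$mutations)[colSums(co$mutations) > 0]
  expect_identical(m, co$mutations[, kept][rownames(m), colnames(m)])

  net <- read_string_links(paths[["network"]], 700)
  expect_equal(net$edges, co$network$edges, tolerance = 1e-9)

  sets <- read_gmt(paths[["genesets"]])
  expect_identical(sets[names(co$genesets)], co$genesets)

  sv <- read.delim(paths[["survival"]], stringsAsFactors = FALSE)
  expect_equal(sv$time, co$survival$time, tolerance = 1e-9)
})
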