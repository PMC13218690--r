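test_that("seed vectors put uniform mass on in-network mutated genes", {
  net <- path_network()
  s <- make_seed(c("A", "C"), net)
  expect_equal(unname(s[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(s), 1)
  expect_equal(attr(s, "n_seed"), 2L)

  s2 <- make_seed(c("A", "NOTAGENE"), net)
  expect_equal(unname(s2["A"]), 1)

  expect_null(make_seed(c("X", "Y"), net))
})

test_that("RWR matches the closed-form linear solve", {
  net <- path_network()
  p0 <- make_seed("A", net)

  # r = 1: pure restart, steady state is the seed itself
  expect_equal(as.numeric(rwr(p0, net, r = 1)), as.numeric(p0))
  expect_equal(attr(rwr(p0, net, r = 1), "iterations"), 1L)

  # path-graph fixture has a known steady state; the default 1e-6 stopping
  # rule leaves a residual of that order, a tighter one reaches 1e-9
  p <- rwr(p0, net, r = 0.75)
  expect_equal(as.numeric(p[c("A", "B", "C")]), c(0.775, 0.200, 0.025),
               tolerance = 1e-6)
  p_tight <- rwr(p0, net, r = 0.75, tol = 1e-12)
  expect_equal(as.numeric(p_tight), rwr_direct(p0, net$transition, 0.75),
               tolerance = 1e-9)

  # 2-node graph, iterative equals direct solve
  two <- build_transition_matrix(gene_network(
    data.frame(from = "A", to = "B", weight = 800)))
  s <- make_seed("A", two)
  expect_equal(as.numeric(rwr(s, two, r = 0.75, tol = 1e-12)),
               rwr_direct(s, two$transition, 0.75), tolerance = 1e-9)

  expect_error(rwr(p0, net, r = 0.75, max_iter = 1L), "converge")
})

test_that("iterative RWR agrees with direct solve on random graphs", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    net <- build_transition_matrix(generate_network(n, 3, seed = rep))
    genes <- sample(net$nodes, sample(1:5, 1))
    p0 <- make_seed(genes, net)
    p <- rwr(p0, net, r = 0.75)
    expect_lt(max(abs(p - rwr_direct(p0, net$transition, 0.75))), 1e-6)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("steady-state mass at the seed is monotone in restart probability", {
  set.seed(3)
  for (rep in 1:5) {
    net <- build_transition_matrix(generate_network(30, 2, seed = rep))
    seed_gene <- sample(net$nodes, 1)
    p0 <- make_seed(seed_gene, net)
    at_seed <- vapply(c(0.1, 0.3, 0.5, 0.75, 0.9),
                      function(r) rwr(p0, net, r = r)[seed_gene], 0)
    expect_true(all(diff(at_seed) > 0))
  }
})

test_that("nodes unreachable from the seed get exactly zero mass", {
  two_comp <- build_transition_matrix(gene_network(data.frame(
    from = c("A", "B", "X"), to = c("B", "C", "Y"), weight = 800)))
  p <- rwr(make_seed("A", two_comp), two_comp, r = 0.75)
  expect_identical(unname(p[c("X", "Y")]), c(0, 0))
})

test_that("cohort propagation is deterministic and reports exclusions", {
  net <- build_transition_matrix(generate_network(40, 3, seed = 5))
  genes <- net$nodes
  m <- matrix(0L, 3, length(genes) + 1,
              dimnames = list(c("P1", "P2", "P3"),
                              c(genes, "OFF_NETWORK")))
  m[1, genes[1:4]] <- 1L
  m[2, genes[1:4]] <- 1L       # identical to P1
  m[3, "OFF_NETWORK"] <- 1L    # empty seed
  prop <- propagate_cohort(m, net)
  expect_equal(rownames(prop$values), c("P1", "P2"))
  expect_equal(prop$values["P1", ], prop$values["P2", ])
  expect_equal(prop$excluded, "P3")
  expect_equal(rowSums(prop$values),
               c(P1 = 1, P2 = 1), tolerance = 1e-9)
  expect_equal(prop$diagnostics$seed_size, c(4L, 4L))

  # batched and single-sample paths agree at a tight tolerance
  prop_tight <- propagate_cohort(m, net, tol = 1e-12)
  single <- rwr(make_seed(genes[1:4], net), net, r = 0.75, tol = 1e-12)
  expect_equal(unname(prop_tight$values["P1", ]),
               unname(as.numeric(single)), tolerance = 1e-9)

  # a sample mutating every network gene propagates the uniform seed
  all_mut <- matrix(1L, 1, length(genes), dimnames = list("ALL", genes))
  p_all <- propagate_cohort(all_mut, net, tol = 1e-12)$values[1, ]
  expect_equal(unname(p_all),
               rwr_direct(rep(1 / length(genes), length(genes)),
                          net$transition, 0.75),
               tolerance = 1e-9)

  expect_error(propagate_cohort(m[3, , drop = FALSE], net), "excluded")
})
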