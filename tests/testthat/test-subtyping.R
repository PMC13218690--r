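test_that("mean silhouette matches hand computation and brute force", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c(1, 1, 2, 2)
  s <- mean_silhouette(pts, lab)
  # a = 1 for every point; b = mean(10, sqrt(101))
  b <- mean(c(10, sqrt(101)))
  expect_equal(s, (b - 1) / b, tolerance = 1e-12)
  expect_equal(round(s, 4), 0.9002)
  expect_equal(s, silhouette_oracle(pts, lab), tolerance = 1e-12)

  set.seed(17)
  for (rep in 1:5) {
    x <- matrix(rnorm(50 * 3), 50, 3)
    l <- sample(1:3, 50, replace = TRUE)
    expect_equal(mean_silhouette(x, l), silhouette_oracle(x, l),
                 tolerance = 1e-12)
  }

  # random labels on a single blob: silhouette near zero
  set.seed(5)
  blob <- matrix(rnorm(200), 100, 2)
  expect_lt(abs(mean_silhouette(blob, rep(1:2, 50))), 0.1)
  # widely separated clusters: silhouette near one
  far <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 50, 0.1), 20))
  expect_gt(mean_silhouette(far, rep(1:2, each = 20)), 0.99)

  expect_error(mean_silhouette(pts, rep(1, 4)), "single cluster")
})

test_that("silhouette-selected k recovers the planted cluster count", {
  pn <- planted_nes(n = 120, p = 8, sep = 4, seed = 2)
  fit <- fit_subtypes(pn$nes, k_range = 2:10, n_init = 10, seed = 2)
  expect_equal(fit$selected_k, 2L)
  expect_gte(mclust::adjustedRandIndex(fit$labels, pn$labels), 0.9)
  expect_equal(names(fit$silhouette_by_k), as.character(2:10))
  expect_true(all(fit$silhouette_by_k >= -1 & fit$silhouette_by_k <= 1))

  # three well-separated blobs
  set.seed(6)
  l3 <- rep(1:3, each = 40)
  x3 <- matrix(rnorm(120 * 6), 120, 6) + 5 * l3
  dimnames(x3) <- list(sprintf("S%03d", 1:120), sprintf("F%d", 1:6))
  expect_equal(fit_subtypes(x3, n_init = 10, seed = 3)$selected_k, 3L)

  # determinism and column-order invariance
  f1 <- fit_subtypes(pn$nes, n_init = 10, seed = 7)
  f2 <- fit_subtypes(pn$nes, n_init = 10, seed = 7)
  f3 <- fit_subtypes(pn$nes[, sample(ncol(pn$nes))], n_init = 10, seed = 7)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$labels, f3$labels)

  degen <- pn$nes; degen[, 1] <- 1
  expect_error(fit_subtypes(degen, n_init = 5, seed = 1), "zero-variance")
})

test_that("labels are oriented so TES 1 has better prognosis", {
  pn <- planted_nes(n = 150, p = 6, sep = 4, seed = 13)
  haz <- ifelse(pn$labels == 1, 0.02, 0.06)  # planted cluster 1 is protective
  sv <- sim_survival(haz, censor_rate = 0.01, seed = 13,
                     ids = rownames(pn$nes))
  fit <- fit_subtypes(pn$nes, n_init = 10, seed = 13, surv = sv)
  rm <- restricted_mean_survival(sv, fit$labels)
  expect_gt(rm[["1"]], rm[["2"]])
  expect_equal(fit$orientation$tes, 1:2)
  # the high-hazard planted cluster must come out as TES 2
  expect_gte(mean(fit$labels[pn$labels == 2] == 2), 0.9)

  # orientation is canonical: renaming input labels changes nothing
  lab <- setNames(pn$labels, rownames(pn$nes))
  swapped <- setNames(3 - pn$labels, rownames(pn$nes))
  o1 <- orient_labels(lab, sv)
  o2 <- orient_labels(swapped, sv)
  expect_identical(as.integer(o1), as.integer(o2))

  # identical KM curves in both clusters: tie broken by cluster size
  sv_tie <- data.frame(sample_id = sprintf("T%02d", 1:6),
                       time = c(1, 2, 1, 2, 1, 2), event = rep(1L, 6),
                       stringsAsFactors = FALSE)
  lab_tie <- setNames(c(1L, 1L, 2L, 2L, 2L, 2L), sv_tie$sample_id)
  o_tie <- orient_labels(lab_tie, sv_tie)
  orient <- attr(o_tie, "orientation")
  expect_equal(orient$original[1], "2")  # larger cluster takes TES 1 on ties
})

test_that("the prognostic filter keeps signal sets and calibrates nulls", {
  set.seed(23)
  n <- 150
  labels <- rep(1:2, length.out = n)
  ids <- sprintf("S%03d", 1:n)
  sv <- sim_survival(0.02 * 3^(labels - 1), censor_rate = 0.01, seed = 23,
                     ids = ids)
  nes <- cbind(
    matrix(labels + rnorm(n * 3, sd = 0.3), n, 3,
           dimnames = list(ids, paste0("PLANTED", 1:3))),
    matrix(rnorm(n * 12), n, 12,
           dimnames = list(ids, paste0("NULL", 1:12)))
  )
  filt <- filter_prognostic_genesets(nes, sv)
  expect_true(all(paste0("PLANTED", 1:3) %in% filt$kept))
  expect_true(all(filt$results$kept == (filt$results$p_value < 0.05)))
  expect_setequal(filt$results$direction[filt$results$beta > 0], "risk")

  # threshold 1 keeps everything
  expect_length(filter_prognostic_genesets(nes, sv, 1)$kept, ncol(nes))

  # survival shuffled: null keep rate compatible with the 5% threshold
  set.seed(99)
  null_nes <- matrix(rnorm(n * 200), n, 200,
                     dimnames = list(ids, paste0("N", 1:200)))
  sv_perm <- sv; sv_perm[, c("time", "event")] <-
    sv[sample(n), c("time", "event")]
  kept_frac <- length(filter_prognostic_genesets(null_nes, sv_perm)$kept) / 200
  expect_lt(abs(kept_frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
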