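# Negative-binomial guide null, alpha-RRA, FDR, and the full screen test

test_that("mean-variance fit recovers Poisson and NB generative laws", {
  set.seed(71)
  mu <- exp(runif(2000, log(10), log(1000)))

  # Poisson replicates: fitted overdispersion negligible
  pois <- matrix(rpois(2000 * 200, mu), nrow = 2000)
  mod <- fit_mean_variance(pois)
  expect_false(mod$fallback_poisson)
  grid <- quantile(mu, seq(0.05, 0.95, 0.1))
  expect_true(all(mod$var_fn(grid) / grid < 1.10))
  expect_true(all(mod$var_fn(grid) / grid >= 1))

  # NB with dispersion 0.2: modeled variance within 25% of truth at deciles
  nb <- matrix(rnbinom(2000 * 50, size = 5, mu = mu), nrow = 2000)
  mod2 <- fit_mean_variance(nb)
  truth <- grid + 0.2 * grid^2
  expect_true(all(abs(mod2$var_fn(grid) / truth - 1) < 0.25))

  # single column: no replicate variance, Poisson fallback
  expect_true(fit_mean_variance(pois[, 1, drop = FALSE])$fallback_poisson)
  # too few usable guides: fallback with warning
  expect_warning(m3 <- fit_mean_variance(matrix(5, nrow = 4, ncol = 3)),
                 "fewer than 10")
  expect_true(m3$fallback_poisson)
})

test_that("guide p-values are exact discrete tails and monotone", {
  pois_model <- fit_mean_variance(matrix(1, nrow = 1, ncol = 1))

  # zero treatment count: P(X >= 0) = 1
  expect_equal(guide_pvalues(10, 0, pois_model), 1)

  # Poisson tail at mean 10, treatment 10 vs brute-force summation
  brute <- sum(exp(-10 + (10:200) * log(10) - lgamma((10:200) + 1)))
  expect_equal(guide_pvalues(10, 10, pois_model), brute, tolerance = 1e-9)

  # larger treatment never gives larger p
  p <- guide_pvalues(rep(50, 60), seq(0, 295, 5), pois_model)
  expect_true(all(diff(p) <= 0))

  # log-scale output agrees with the natural scale where both representable
  lp <- guide_pvalues(10, 30, pois_model, log.p = TRUE)
  expect_equal(exp(lp), guide_pvalues(10, 30, pois_model), tolerance = 1e-12)
})

test_that("alpha-RRA agrees with the exhaustive permutation oracle", {
  # worked instance: 6 guides, the gene owns the two smallest ranks,
  # alpha = 0.5 -> exhaustive p over C(6,2) = 15 assignments is 1/15
  p_all <- c(0.01, 0.02, 0.2, 0.3, 0.6, 0.7)
  gs <- data.frame(guide_id = sprintf("g%d", 1:6),
                   gene = c("A", "A", "B", "B", "C", "C"),
                   p_enrich = p_all, stringsAsFactors = FALSE)
  oracle <- exhaustive_rra(p_all, gene_idx = 1:2, alpha = 0.5)
  expect_equal(oracle$p_exact, 1 / 15)
  res <- alpha_rra(gs, alpha = 0.5, n_perm = 10000, seed = 1)
  pA <- res$p_value[res$gene == "A"]
  se <- sqrt(oracle$p_exact * (1 - oracle$p_exact) / 10000)
  expect_lt(abs(pA - oracle$p_exact), 3 * se + 2 / 10001)

  # random small instances, all with <= 8 guides total
  set.seed(72)
  for (rep in 1:8) {
    n <- sample(3:8, 1)
    k <- sample(1:min(4, n - 1), 1)
    p_all <- round(runif(n), 4)
    while (anyDuplicated(p_all)) p_all <- round(runif(n), 4)
    genes <- rep("other", n); genes[seq_len(k)] <- "target"
    gs <- data.frame(guide_id = sprintf("g%d", seq_len(n)), gene = genes,
                     p_enrich = p_all, stringsAsFactors = FALSE)
    alpha <- sample(c(0.3, 0.5, 0.8), 1)
    oracle <- exhaustive_rra(p_all, seq_len(k), alpha)
    res <- alpha_rra(gs, alpha = alpha, n_perm = 10000, seed = rep,
                     test_genes = "target")
    se <- sqrt(max(oracle$p_exact * (1 - oracle$p_exact), 1e-6) / 10000)
    expect_lt(abs(res$p_value - oracle$p_exact), 4 * se + 2 / 10001)
    expect_equal(res$rra_rho, oracle$obs, tolerance = 1e-12)
  }
})

test_that("alpha-RRA degenerate and monotonicity behavior", {
  # gene with no guide below alpha: rho 1, permutation p large
  gs <- data.frame(guide_id = sprintf("g%d", 1:10),
                   gene = rep(c("A", "B"), each = 5),
                   p_enrich = seq(0.5, 0.95, 0.05), stringsAsFactors = FALSE)
  res <- alpha_rra(gs, alpha = 0.4, n_perm = 1000, seed = 3)
  expect_true(all(res$rra_rho == 1))
  expect_true(all(res$p_value >= 0.5))
  expect_true(all(res$n_selected == 0))

  # decreasing one guide's p never increases the gene's rho
  base <- data.frame(guide_id = sprintf("g%d", 1:12),
                     gene = rep(c("A", "B", "C"), each = 4),
                     p_enrich = c(0.02, 0.2, 0.5, 0.9,
                                  0.04, 0.3, 0.6, 0.8,
                                  0.05, 0.4, 0.7, 0.95),
                     stringsAsFactors = FALSE)
  rho0 <- alpha_rra(base, alpha = 0.3, n_perm = 1000, seed = 4)
  for (newp in c(0.01, 0.005, 0.001)) {
    mod <- base
    mod$p_enrich[2] <- newp  # guide of gene A moves toward rank 1
    rho1 <- alpha_rra(mod, alpha = 0.3, n_perm = 1000, seed = 4)
    expect_lte(rho1$rra_rho[rho1$gene == "A"], rho0$rra_rho[rho0$gene == "A"])
  }

  # a gene with zero guides is an error
  expect_error(alpha_rra(base, alpha = 0.3, n_perm = 1000, seed = 1,
                         test_genes = c("A", "Z")), "zero guides")
})

test_that("BH adjustment follows the hand-worked example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- runif(50)
  f <- bh_fdr(p)
  ord <- order(p)
  expect_true(all(diff(f[ord]) >= 0))
  expect_true(all(f >= p))
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("screen test: null self-comparison calls nothing", {
  lib <- sim_guide_library(n_genes = 100, guides_per_gene = 4, n_controls = 5,
                           seed = 81)
  scr <- simulate_screen(lib, sim_config(n_genes = 100, guides_per_gene = 4,
                                         n_cells = 2e4, reads_per_sample = 2e5,
                                         seed = 81))
  counts <- scr$counts
  dup <- counts
  dup$counts <- cbind(counts$counts,
                      treatment = counts$counts[, "plasmid"])
  fit <- screen_test(dup, "plasmid", "treatment", n_perm = 1000, seed = 82)
  expect_equal(sum(fit$results$fdr <= 0.1), 0)
  expect_error(screen_test(dup, "plasmid", "plasmid"), "same column")
  expect_error(screen_test(dup, "plasmid", "nope"), "unknown sample")
})

test_that("screen test recovers planted hits and honors exclusions", {
  hits <- c("G0007", "G0205", "G0444")
  lib <- sim_guide_library(n_genes = 500, guides_per_gene = 5, n_controls = 20,
                           seed = 91)
  scr <- simulate_screen(lib, sim_config(n_genes = 500, hit_genes = hits,
                                         n_cells = 1e5, reads_per_sample = 1e6,
                                         seed = 92))
  fit <- screen_test(scr$counts, "plasmid", "sorted", seed = 93)
  res <- fit$results
  expect_setequal(res$gene[1:3], hits)
  expect_true(all(res$fdr[1:3] <= 0.1))
  expect_false("non-targeting" %in% res$gene)
  expect_equal(res$rank, seq_len(nrow(res)))

  # excluded genes are absent from the output
  fit2 <- screen_test(scr$counts, "plasmid", "sorted", seed = 93,
                      exclude_genes = c("G0007", "G0100"))
  expect_false(any(c("G0007", "G0100") %in% fit2$results$gene))

  # summary and plot methods work on the fitted object
  s <- summary(fit)
  expect_true(all(hits %in% s$candidates))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("screen test output is deterministic and order-invariant", {
  lib <- sim_guide_library(n_genes = 60, guides_per_gene = 4, n_controls = 5,
                           seed = 95)
  scr <- simulate_screen(lib, sim_config(n_genes = 60, guides_per_gene = 4,
                                         hit_genes = "G0005", n_cells = 2e4,
                                         reads_per_sample = 2e5, seed = 95))
  f1 <- screen_test(scr$counts, "plasmid", "sorted", n_perm = 1000, seed = 7)
  f2 <- screen_test(scr$counts, "plasmid", "sorted", n_perm = 1000, seed = 7)
  expect_identical(f1$results, f2$results)

  # permuting guide rows changes nothing
  perm <- sample(nrow(scr$counts$counts))
  shuf <- scr$counts
  shuf$counts <- shuf$counts[perm, ]
  shuf$guides <- shuf$guides[perm, ]
  rownames(shuf$guides) <- NULL
  f3 <- screen_test(shuf, "plasmid", "sorted", n_perm = 1000, seed = 7)
  expect_identical(f1$results, f3$results)
})

test_that("replicate treatments are combined per guide", {
  lib <- sim_guide_library(n_genes = 50, guides_per_gene = 3, n_controls = 4,
                           seed = 97)
  scr <- simulate_screen(lib, sim_config(n_genes = 50, guides_per_gene = 3,
                                         hit_genes = "G0001", n_cells = 2e4,
                                         reads_per_sample = 2e5, seed = 97))
  cnt <- scr$counts
  cnt$counts <- cbind(cnt$counts, sorted2 = cnt$counts[, "sorted"])
  fit <- screen_test(cnt, "plasmid", c("sorted", "sorted2"),
                     n_perm = 1000, seed = 5)
  # duplicated replicate: median equals the single-replicate p-values
  fit1 <- screen_test(cnt, "plasmid", "sorted", n_perm = 1000, seed = 5)
  expect_equal(fit$guide_stats$p_log, fit1$guide_stats$p_log)
  expect_identical(fit$results, fit1$results)
})
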