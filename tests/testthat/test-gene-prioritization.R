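test_that("gene set intersection is exact set algebra with case normalization", {
  expect_length(intersect_gene_sets(c("A", "B"), c("C", "D")), 0L)
  s <- gene_set(c("add3", " ADD1", "MYC"))
  expect_setequal(as.character(intersect_gene_sets(s, s)), as.character(s))
  # planted overlap between large random symbol sets
  set.seed(4)
  shared <- sprintf("SH%03d", 1:30)
  a <- c(sprintf("A%05d", 1:8479), shared)
  b <- c(sprintf("B%03d", 1:15), shared)
  out <- intersect_gene_sets(sample(a), sample(tolower(b)))
  expect_setequal(as.character(out), shared)
  expect_equal(unname(attr(out, "coverage")["b"]), 30 / 45)
})

test_that("hypergeometric upper tail matches enumeration and known values", {
  # adducin enrichment: N = 19396 protein-coding genes, 3 adducins,
  # 30 selected, 3 hits
  expect_equal(signif(hypergeom_upper_tail(19396, 3, 30, 3), 3), 3.34e-9)
  expect_identical(hypergeom_upper_tail(100, 10, 5, 0), 1)
  expect_equal(hypergeom_upper_tail(10, 3, 4, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(oracle_hypergeom(10, 3, 4, 2), 1 / 3, tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(10, 3, 4, 5), "cannot exceed")
  expect_error(hypergeom_upper_tail(10, 11, 4, 2), "cannot exceed")
  # monotone non-increasing in x
  p <- vapply(0:3, function(x) hypergeom_upper_tail(50, 6, 10, x), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("separated point masses are gated exactly", {
  x <- setNames(c(0, 0, 0, 0, 0, 10, 10, 10, 10, 10), paste0("g", 1:10))
  fit <- fit_bimodal_gate(x, seed = 1)
  expect_setequal(fit$gated_high, paste0("g", 6:10))
  expect_lt(abs(fit$means["low"] - 0), 0.1)
  expect_lt(abs(fit$means["high"] - 10), 0.1)
  expect_error(fit_bimodal_gate(setNames(rep(2, 20), paste0("g", 1:20))),
               "degenerate")
})

test_that("the mixture gate recovers planted components and is shift invariant", {
  set.seed(9)
  n <- 500; pi_high <- 0.6
  hi <- runif(n) < pi_high
  x <- setNames(ifelse(hi, rnorm(n, 6, 1), rnorm(n, 1, 0.25)), paste0("g", 1:n))
  fit <- fit_bimodal_gate(x, seed = 3)
  se_mu_low <- 0.25 / sqrt(sum(!hi)); se_mu_high <- 1 / sqrt(sum(hi))
  expect_lte(abs(fit$means["low"] - 1), 3 * se_mu_low + 0.02)
  expect_lte(abs(fit$means["high"] - 6), 3 * se_mu_high + 0.02)
  se_frac <- sqrt(pi_high * (1 - pi_high) / n)
  expect_lte(abs(length(fit$gated_high) / n - pi_high), 3 * se_frac)
  # gate membership is invariant to adding a constant
  fit2 <- fit_bimodal_gate(x + 100, seed = 3)
  expect_setequal(fit2$gated_high, fit$gated_high)
  # deterministic given the seed
  expect_identical(fit_bimodal_gate(x, seed = 3)$posterior_high,
                   fit$posterior_high)
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attachment
  set.seed(12)
  x <- setNames(c(rnorm(200, 1, 0.3), rnorm(300, 5, 0.8)), paste0("g", 1:500))
  fit <- fit_bimodal_gate(x, seed = 2)
  mc <- mclust::Mclust(unname(x), G = 2, modelNames = "V", verbose = FALSE)
  mu_mc <- sort(mc$parameters$mean)
  expect_lt(abs(fit$means["low"] - mu_mc[1]), 0.1)
  expect_lt(abs(fit$means["high"] - mu_mc[2]), 0.1)
  gate_mc <- names(x)[mc$z[, which.max(mc$parameters$mean)] > 0.5]
  expect_gt(length(intersect(fit$gated_high, gate_mc)) /
            length(union(fit$gated_high, gate_mc)), 0.98)
})

test_that("manual threshold gating bypasses the mixture", {
  x <- setNames(seq(0, 9.5, by = 0.5), paste0("g", 1:20))
  fit <- fit_bimodal_gate(x, manual_threshold = 5)
  expect_setequal(fit$gated_high, names(x)[x > 5])
})

test_that("dependency scaling hits its anchor identities exactly", {
  set.seed(6)
  genes <- sprintf("G%03d", 1:60)
  dep <- matrix(rnorm(60 * 5, 0, 0.5), 60, 5,
                dimnames = list(genes, paste0("L", 1:5)))
  ess <- genes[1:10]; non <- genes[11:20]
  sc <- scale_dependency(dep, ess, non)
  for (ln in 1:5) {
    expect_equal(unname(
      (sc$m_non[ln] - sc$m_non[ln]) / (sc$m_non[ln] - sc$m_ess[ln])), 0)
    # scaling the anchor medians themselves gives exactly 0 and -1
    expect_equal(unname(median(sc$scaled[ess, ln])), -1, tolerance = 1e-12)
    expect_equal(unname(median(sc$scaled[non, ln])), 0, tolerance = 1e-12)
  }
  # affine midpoint and brute-force agreement
  expect_equal(unname((-0.4 - 0) / (0 - -0.8)), -0.5)
  brute <- dep
  for (ln in 1:5) brute[, ln] <- (dep[, ln] - sc$m_non[ln]) /
    (sc$m_non[ln] - sc$m_ess[ln])
  expect_equal(sc$scaled, brute, tolerance = 1e-12)
  # degenerate anchors are fatal, naming the line
  dep2 <- dep; dep2[1:20, 2] <- 0
  expect_error(scale_dependency(dep2, ess, non), "L2")
})

test_that("prioritization ranks the planted dependent gene first", {
  om <- generate_omics_tables(omics_sim_spec(n_genes = 400, n_lines = 12,
                                             planted_dependent_gene = 42,
                                             planted_line = 5, seed = 14))
  shared <- gene_set(rownames(om$expression))
  pr <- prioritize_genes(shared, om$expression, om$dependency,
                         om$core_fitness, om$anchors, seed = 2)
  expect_equal(pr$report$gene[1], om$ground_truth$planted_dependent_gene)
  expect_equal(pr$report$argmin_line[1], om$ground_truth$planted_line)
  expect_true(all(diff(pr$report$min_scaled_dep) >= 0))
  # ranking is invariant to a common affine transform of one line
  dep2 <- om$dependency
  dep2[, 3] <- 2.5 * dep2[, 3] + 1
  pr2 <- prioritize_genes(shared, om$expression, dep2,
                          om$core_fitness, om$anchors, seed = 2)
  expect_identical(pr2$report$gene, pr$report$gene)
})

test_that("all-core-fitness input yields an empty report, not an error", {
  om <- generate_omics_tables(omics_sim_spec(n_genes = 100, n_lines = 6,
                                             seed = 4))
  pr <- prioritize_genes(gene_set(rownames(om$expression)), om$expression,
                         om$dependency,
                         core_fitness = gene_set(rownames(om$expression)),
                         om$anchors, seed = 1)
  expect_equal(nrow(pr$report), 0L)
  # missing genes are reported, not fatal
  pr2 <- prioritize_genes(gene_set(c(rownames(om$expression)[1:15], "NOTHERE")),
                          om$expression, om$dependency,
                          gene_set(character(0)), om$anchors, seed = 1)
  expect_equal(pr2$missing_genes, "NOTHERE")
})

test_that("signature correlations separate planted sets from the null", {
  set.seed(31)
  n_lines <- 48; n_genes <- 150
  z <- matrix(rnorm(n_genes * n_lines), n_genes, n_lines,
              dimnames = list(sprintf("G%03d", 1:n_genes),
                              sprintf("L%02d", 1:n_lines)))
  focal <- "G001"
  # planted up-set: focal profile + noise at target r = 0.7
  r <- 0.7
  for (i in 2:11)
    z[i, ] <- r * z[1, ] + sqrt(1 - r^2) * rnorm(n_lines)
  up <- rownames(z)[2:11]; down <- rownames(z)[100:109]
  out <- signature_correlation_test(z, focal, up, down)
  se_r <- (1 - r^2) / sqrt(n_lines)  # approximate SE of a correlation
  expect_lte(abs(out$mean_r_up - r), 3 * se_r)
  expect_lt(out$p_up, 0.01)
  # independent genes: null-consistent correlations
  se0 <- 1 / sqrt(n_lines - 1)
  expect_lte(abs(out$mean_r_down - 0), 3 * se0 / sqrt(10) + 0.1)
  expect_gt(out$p_down, 0.001)
  # identical profile correlates at exactly 1
  z2 <- rbind(z, COPY = z[1, ])
  out2 <- signature_correlation_test(z2, focal, gene_set("COPY"), down)
  expect_equal(out2$up$r, 1)
  # constant genes are excluded with a warning
  z3 <- rbind(z, FLAT = rep(2, n_lines))
  expect_warning(signature_correlation_test(z3, focal, up, down), "constant")
})
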