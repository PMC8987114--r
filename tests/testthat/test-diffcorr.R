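# Differential-correlation engine: Fisher z-test, per-correlation p-values,
# local FDR, the pairwise scan, switch filtering, and eigen-molecule
# submodule networks.

test_that("fisher z-test: equal correlations give z = 0, p = 1", {
  fz <- fisher_z_test(0.5, 50, 0.5, 80)
  expect_equal(fz$z_stat, 0)
  expect_equal(fz$p_diff, 1)
})

test_that("fisher z-test matches an independent evaluation of the formula", {
  # strongly reversed pair at case-control sample sizes 156 / 82
  r1 <- 0.406621495; r2 <- -0.728163034
  fz <- fisher_z_test(r1, 156, r2, 82)
  z_oracle <- (0.5 * log((1 + r1) / (1 - r1)) - 0.5 * log((1 + r2) / (1 - r2))) /
    sqrt(1 / 153 + 1 / 79)
  expect_equal(fz$z_stat, z_oracle, tolerance = 1e-12)
  expect_lt(fz$p_diff, 1e-15)
})

test_that("fisher z-test is antisymmetric under condition exchange", {
  set.seed(21)
  for (rep in 1:20) {
    r1 <- runif(1, -0.95, 0.95); r2 <- runif(1, -0.95, 0.95)
    n1 <- sample(10:200, 1); n2 <- sample(10:200, 1)
    a <- fisher_z_test(r1, n1, r2, n2)
    b <- fisher_z_test(r2, n2, r1, n1)
    expect_equal(a$z_stat, -b$z_stat, tolerance = 1e-12)
    expect_equal(a$p_diff, b$p_diff, tolerance = 1e-12)
  }
})

test_that("fisher z-test clamps |r| = 1 with a warning and rejects |r| > 1", {
  expect_warning(fz <- fisher_z_test(1, 20, 0.5, 20), "clamped")
  expect_true(is.finite(fz$z_stat))
  expect_error(fisher_z_test(1.2, 20, 0.5, 20), "outside")
  expect_error(fisher_z_test(0.5, 3, 0.5, 20), "n >= 4")
})

test_that("correlation p-values match the t CDF closed form on a grid", {
  for (r in c(-0.9, -0.5, -0.1, 0, 0.3, 0.7, 0.95)) {
    for (n in c(5, 10, 50, 200)) {
      t <- r * sqrt((n - 2) / (1 - r^2))
      expect_equal(correlation_p(r, n), 2 * pt(-abs(t), n - 2),
                   tolerance = 1e-10)
    }
  }
  expect_equal(correlation_p(0, 30), 1)
  expect_lt(correlation_p(0.99, 100), 1e-10)
})

test_that("local fdr is calibrated on pure-null z-values", {
  fracs <- sapply(1:10, function(s) {
    set.seed(s)
    l <- local_fdr(rnorm(5000))
    c(mean(l < 0.05), mean(l))
  })
  expect_lte(max(fracs[1, ]), 0.01)
  expect_gte(min(fracs[2, ]), 0.9)
})

test_that("local fdr flags a shifted mixture component", {
  set.seed(31)
  z <- c(rnorm(4750), rnorm(250, mean = 6))
  l <- local_fdr(z)
  expect_gt(mean(l[4751:5000] < 0.05), 0.9)
  expect_gt(attr(l, "pi0"), 0.85)
  expect_true(all(l >= 1e-300))  # never a hard zero
})

test_that("local fdr is monotone non-increasing in |z|", {
  set.seed(32)
  z <- c(rnorm(1000), rnorm(50, 5), rnorm(50, -5))
  l <- local_fdr(z)
  ord <- order(abs(z))
  expect_true(all(diff(l[ord]) <= 1e-12))
})

test_that("degenerate or tiny inputs fall back to Benjamini-Hochberg", {
  expect_message(l <- local_fdr(rep(1.3, 500)), "Benjamini-Hochberg")
  expect_identical(attr(l, "method"), "bh")
  expect_message(l2 <- local_fdr(rnorm(20)), "Benjamini-Hochberg")
  expect_identical(attr(l2, "method"), "bh")
  expect_warning(local_fdr(rnorm(100)), "unstable")
})

test_that("split_by_condition partitions columns and preserves gene order", {
  sim <- simulate_expression(n_genes = 20, module_sizes = c(10, 10),
                             trait_modules = integer(0), seed = 33)
  sp <- split_by_condition(sim$expr, sim$traits)
  expect_identical(ncol(sp$cond1), 150L)
  expect_identical(ncol(sp$cond2), 80L)
  expect_identical(rownames(sp$cond1), rownames(sim$expr))
  expect_identical(rownames(sp$cond2), rownames(sim$expr))
  tr_bad <- sim$traits
  tr_bad[tr_bad == 0] <- 1L
  tr_bad[1:3] <- 0L
  expect_error(split_by_condition(sim$expr, tr_bad), "n - 3 > 0")
})

test_that("diffcorr scan: pair count, identical conditions, and sorting", {
  sim <- simulate_expression(n_genes = 5, module_sizes = c(5),
                             trait_modules = integer(0),
                             n_samples = c(20, 20), seed = 34)
  sp <- split_by_condition(sim$expr, sim$traits)
  tab <- suppressMessages(suppressWarnings(
    diffcorr_scan(sp$cond1, sp$cond2)))
  expect_identical(nrow(tab), 10L)  # 5 choose 2
  expect_true(all(tab$gene_a < tab$gene_b))
  expect_true(!is.unsorted(tab$lfdr))

  same <- suppressMessages(suppressWarnings(
    diffcorr_scan(sp$cond1, sp$cond1)))
  expect_equal(same$z_stat, rep(0, 10))
  expect_equal(same$p_diff, rep(1, 10))
})

test_that("scan recovers planted switch pairs and swapping conditions negates z", {
  results <- lapply(1:10, function(s) {
    sim <- simulate_expression(n_genes = 50, module_sizes = 50L, rho = 0.6,
                               trait_modules = integer(0), n_switch_pairs = 10,
                               seed = s)
    sp <- split_by_condition(sim$expr, sim$traits)
    tab <- suppressWarnings(diffcorr_scan(sp$cond1, sp$cond2))
    score_switch_recovery(tab, sim$truth)
  })
  recalls <- vapply(results, `[[`, 0, "recall")
  fdrs <- vapply(results, `[[`, 0, "empirical_fdr")
  expect_gte(sum(recalls >= 0.9 & fdrs <= 0.1), 9L)

  sim <- simulate_expression(n_genes = 30, module_sizes = 30L, rho = 0.6,
                             trait_modules = integer(0), n_switch_pairs = 5,
                             seed = 99)
  sp <- split_by_condition(sim$expr, sim$traits)
  fwd <- suppressWarnings(diffcorr_scan(sp$cond1, sp$cond2))
  rev <- suppressWarnings(diffcorr_scan(sp$cond2, sp$cond1))
  key <- function(t) paste(t$gene_a, t$gene_b)
  rev <- rev[match(key(fwd), key(rev)), ]
  expect_equal(rev$z_stat, -fwd$z_stat, tolerance = 1e-12)
  expect_equal(rev$p_diff, fwd$p_diff, tolerance = 1e-12)
  expect_identical(rev$switched, fwd$switched)
})

test_that("zero-variance genes are excluded from the scan with a warning", {
  sim <- simulate_expression(n_genes = 10, module_sizes = 10L,
                             trait_modules = integer(0),
                             n_samples = c(10, 10), seed = 35)
  expr <- sim$expr
  expr["G0003", sim$traits == 1] <- 7
  sp <- split_by_condition(expr, sim$traits)
  expect_warning(tab <- suppressMessages(diffcorr_scan(sp$cond1, sp$cond2)),
                 "G0003")
  expect_false("G0003" %in% c(tab$gene_a, tab$gene_b))
})

test_that("switched_pairs applies both the sign and lfdr filters", {
  tab <- data.frame(gene_a = c("a", "a", "a"), gene_b = c("b", "c", "d"),
                    r1 = c(0.4, 0.4, 0.4), r2 = c(-0.7, 0.1, -0.7),
                    lfdr = c(0.001, 0.001, 0.2),
                    switched = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  out <- switched_pairs(tab, 0.05)
  expect_identical(out$gene_b, "b")
})

test_that("type-I error of the z-test is nominal under a shared-correlation null", {
  set.seed(36)
  frac <- sapply(1:10, function(s) {
    rs <- null_pair_correlations(2000, 150, 80, 0.5)
    fz <- fisher_z_test(rs$r1, 150, rs$r2, 80)
    mean(fz$p_diff < 0.05)
  })
  expect_gte(mean(frac), 0.04)
  expect_lte(mean(frac), 0.06)
})

test_that("eigen-molecule networks split two independent factors", {
  set.seed(37)
  n <- 100
  f1 <- rnorm(n); f2 <- rnorm(n)
  expr <- rbind(
    t(replicate(10, sqrt(0.8) * f1 + sqrt(0.2) * rnorm(n))),
    t(replicate(10, sqrt(0.8) * f2 + sqrt(0.2) * rnorm(n))))
  dimnames(expr) <- list(sprintf("g%02d", 1:20), sprintf("s%03d", 1:n))
  emn <- eigen_molecule_network(expr, rownames(expr), n_submodules = 2)
  truth <- rep(c("x", "y"), each = 10)
  expect_gte(mclust::adjustedRandIndex(emn$membership, truth), 0.9)

  all_edges <- eigen_molecule_network(expr, rownames(expr), 2,
                                      edge_threshold = 0)
  expect_identical(nrow(all_edges$edges), 1L)  # complete graph on 2 nodes
  no_edges <- eigen_molecule_network(expr, rownames(expr), 2,
                                     edge_threshold = 1.01)
  expect_identical(nrow(no_edges$edges), 0L)
})
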