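# Module detection, eigengenes, trait association, GS/MM and key-module
# selection.

sim_default <- simulate_expression(seed = 101)
dist_default <- dist_tom(tom(adjacency(correlation_matrix(sim_default$expr), 5)))

test_that("sample outlier screening keeps homogeneous data intact", {
  sim <- simulate_expression(trait_modules = integer(0), seed = 11)
  sc <- cluster_samples(sim$expr)
  expect_identical(sc$kept, colnames(sim$expr))
  expect_length(sc$removed, 0L)
})

test_that("a +10 SD shifted sample is removed, and only that sample", {
  sim <- simulate_expression(trait_modules = integer(0), seed = 12)
  expr <- sim$expr
  expr[, "S010"] <- expr[, "S010"] + 10
  expect_message(sc <- cluster_samples(expr), "S010")
  expect_identical(sc$removed, "S010")
})

test_that("cut quantile 1 retains every sample", {
  sim <- simulate_expression(seed = 13)
  expr <- sim$expr
  expr[, "S001"] <- expr[, "S001"] + 10
  sc <- cluster_samples(expr, cut_height_quantile = 1)
  expect_identical(sc$kept, colnames(expr))
})

test_that("planted modules are recovered with high ARI and background stays grey", {
  det <- detect_modules(dist_default, min_module_size = 30)
  found <- det$modules
  expect_gte(score_module_recovery(found, sim_default$truth), 0.9)
  expect_gte(length(setdiff(unique(found), "grey")), 4L)
  # grey should be dominated by planted background
  grey_genes <- names(found)[found == "grey"]
  frac_bg <- mean(sim_default$truth$module_of_gene[grey_genes] == 0)
  expect_gt(frac_bg, 0.8)
})

test_that("module labels are deterministic and size-ordered", {
  d1 <- detect_modules(dist_default, 30)
  d2 <- detect_modules(dist_default, 30)
  expect_identical(d1$modules, d2$modules)
  sizes <- table(d1$modules[d1$modules != "grey"])
  ord <- intersect(dccnet:::module_colors, names(sizes))
  expect_true(all(diff(as.integer(sizes[ord])) <= 0))
})

test_that("an oversized minimum module size makes everything grey", {
  expect_warning(det <- detect_modules(dist_default, min_module_size = 200),
                 "grey")
  expect_true(all(det$modules == "grey"))
})

test_that("equal-size modules get deterministic labels via the gene-id tie-break", {
  sim <- simulate_expression(n_genes = 60, module_sizes = c(20, 20),
                             rho = 0.8, trait_modules = integer(0),
                             n_samples = c(60, 60), seed = 14)
  D <- dist_tom(tom(adjacency(correlation_matrix(sim$expr), 5)))
  det <- detect_modules(D, min_module_size = 10)
  m <- det$modules[det$modules != "grey"]
  # two equal-size modules: turquoise must hold the smallest member id
  expect_setequal(unique(m), c("turquoise", "blue"))
  expect_true(min(names(m)[m == "turquoise"]) < min(names(m)[m == "blue"]))
})

test_that("eigengenes are unit-norm, sign-fixed and recover the module factor", {
  det <- detect_modules(dist_default, 30)
  me <- module_eigengenes(sim_default$expr, det$modules)
  for (lab in colnames(me$eigengenes)) {
    e <- me$eigengenes[, lab]
    expect_equal(sum(e^2), 1, tolerance = 1e-9)
    members <- names(det$modules)[det$modules == lab]
    Z <- t(scale(t(sim_default$expr[members, ])))
    expect_gte(cor(e, colMeans(Z)), 0)
    # variance explained at least what the mean profile achieves (PC1 optimality)
    mp <- colMeans(Z) / sqrt(sum(colMeans(Z)^2))
    ve_mean <- sum((Z %*% mp)^2) / sum(Z^2)
    expect_gte(me$var_explained[[lab]] + 1e-12, ve_mean)
  }
})

test_that("a rank-1 module yields its profile with variance explained ~ 1", {
  set.seed(15)
  x <- rnorm(30)
  expr <- rbind(g1 = 2 * x + 1, g2 = -3 * x, g3 = 0.5 * x + 4)
  colnames(expr) <- sprintf("s%02d", 1:30)
  me <- module_eigengenes(expr, setNames(rep("blue", 3), rownames(expr)))
  expect_gt(me$var_explained[["blue"]], 0.999)
  expect_gt(abs(cor(me$eigengenes[, "blue"], x)), 0.999)
})

test_that("eigengene tracks the generating factor on planted data", {
  # module 1 is trait-linked (delta = +1); its factor is the case-shifted one
  det <- detect_modules(dist_default, 30)
  me <- module_eigengenes(sim_default$expr, det$modules)
  truth_m1 <- names(sim_default$truth$module_of_gene)[
    sim_default$truth$module_of_gene == 1]
  lab <- names(which.max(table(det$modules[truth_m1])))
  members <- names(det$modules)[det$modules == lab]
  proxy <- colMeans(sim_default$expr[members, ])  # factor proxy
  expect_gte(abs(cor(me$eigengenes[, lab], proxy)), 0.95)
})

test_that("module-trait p-values agree with the t-distribution closed form", {
  set.seed(16)
  for (rep in 1:20) {
    e <- rnorm(20)
    tr <- rep(c(1L, 0L), each = 10)
    r <- cor(e, tr)
    p_oracle <- 2 * pt(-abs(r * sqrt(18 / (1 - r^2))), df = 18)
    me <- structure(list(eigengenes = matrix(e, 20, 1,
                                             dimnames = list(sprintf("s%02d", 1:20), "blue")),
                         var_explained = c(blue = 1), sizes = c(blue = 5L)),
                    class = "module_eigengenes")
    mt <- module_trait(me, setNames(tr, sprintf("s%02d", 1:20)))
    expect_equal(mt$p, p_oracle, tolerance = 1e-10)
  }
})

test_that("module-trait extremes behave: perfect association and orthogonality", {
  n <- 20
  tr <- setNames(rep(c(1L, 0L), each = n / 2), sprintf("s%02d", 1:n))
  mk <- function(e) structure(
    list(eigengenes = matrix(e, n, 1, dimnames = list(names(tr), "m")),
         var_explained = c(m = 1), sizes = c(m = 5L)),
    class = "module_eigengenes")
  perfect <- module_trait(mk(as.numeric(tr)), tr)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  expect_lt(perfect$p, 1e-30)
  orth <- module_trait(mk(rep(c(-1, 1), n / 2)), tr)  # balanced within classes
  expect_equal(orth$r, 0, tolerance = 1e-12)
  expect_equal(orth$p, 1, tolerance = 1e-9)
  expect_error(module_trait(mk(rnorm(n)), setNames(rep(1L, n), names(tr))),
               "constant")
})

test_that("GS/MM: self-eigengene gives MM 1; null genes have small GS", {
  det <- detect_modules(dist_default, 30)
  me <- module_eigengenes(sim_default$expr, det$modules)
  lab <- colnames(me$eigengenes)[1L]
  expr2 <- rbind(sim_default$expr, EGENE = me$eigengenes[, lab])
  mods2 <- c(det$modules, EGENE = lab)
  gm <- gene_significance_mm(expr2, sim_default$traits, me, mods2)
  expect_equal(unname(gm$mm[["EGENE"]]), 1, tolerance = 1e-9)
  # background genes are trait-independent: GS small at n = 230
  bg <- names(sim_default$truth$module_of_gene)[
    sim_default$truth$module_of_gene == 0]
  expect_lt(max(gm$gs[bg]), 0.25)
  expect_lt(mean(gm$gs[bg]), 0.1)
})

test_that("trait-linked modules show positive GS-MM correlation over members", {
  # with equal factor loadings the population GS and MM are the same for
  # every member, so only the sampling-level association remains: genes
  # whose realised profile tracks the factor more closely score higher on
  # both. The correlation is therefore positive but modest.
  vals <- vapply(1:10, function(s) {
    sim <- simulate_expression(seed = s)
    det <- detect_modules(dist_tom(tom(adjacency(
      correlation_matrix(sim$expr), 5))), 30)
    me <- module_eigengenes(sim$expr, det$modules)
    gm <- gene_significance_mm(sim$expr, sim$traits, me, det$modules)
    m1 <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene == 1]
    lab <- names(which.max(table(det$modules[m1])))
    gm$gs_mm_cor[[lab]]
  }, 0)
  expect_gt(mean(vals), 0.1)
  expect_gte(sum(vals > -0.05), 9L)
})

test_that("key-module selection picks extremes with tie-breaks and errors", {
  mt <- data.frame(module = c("blue", "darkred", "tan"),
                   r = c(0.88, -0.77, 0.10),
                   p = c(2e-78, 2e-48, 0.4), n = 238,
                   size = c(100L, 60L, 40L), stringsAsFactors = FALSE)
  key <- select_key_modules(mt)
  expect_identical(key, list(positive = "blue", negative = "darkred"))

  all_pos <- transform(mt, r = abs(r), p = c(1e-5, 1e-4, 0.4))
  expect_error(select_key_modules(all_pos), "negatively")
  key2 <- select_key_modules(all_pos, allow_single = TRUE)
  expect_identical(key2$positive, "blue")
  expect_true(is.na(key2$negative))

  tied <- data.frame(module = c("a", "b", "c"), r = c(0.5, 0.5, -0.4),
                     p = c(1e-6, 1e-6, 1e-4), n = 100,
                     size = c(30L, 80L, 50L), stringsAsFactors = FALSE)
  expect_identical(select_key_modules(tied)$positive, "b")  # larger module wins
})
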