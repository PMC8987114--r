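# Differential-correlation engine: per-condition correlations, Fisher
# z-test for equality of two correlations, empirical-Bayes local FDR,
# sign-switch classification, and eigen-molecule submodule networks.
#
# Correlations are SIGNED throughout this stage (network construction is
# unsigned, but a sign switch is only observable on signed correlations).

#' Split an expression matrix by binary condition
#'
#' @param expr Expression matrix, genes in rows.
#' @param traits Named 0/1 trait vector over `colnames(expr)`
#'   (1 = condition 1 / case, 0 = condition 2 / control).
#' @return List with `cond1` and `cond2` column-subset matrices (gene order
#'   preserved).
#' @export
split_by_condition <- function(expr, traits) {
  traits <- traits[colnames(expr)]
  if (anyNA(traits)) stop("traits missing for some samples of the matrix")
  n1 <- sum(traits == 1L); n2 <- sum(traits == 0L)
  if (n1 < 4L || n2 < 4L) {
    stop(sprintf("both conditions need >= 4 samples (got %d/%d); Fisher's z requires n - 3 > 0",
                 n1, n2))
  }
  list(cond1 = expr[, traits == 1L, drop = FALSE],
       cond2 = expr[, traits == 0L, drop = FALSE])
}

# clamp correlations at +/- (1 - 1e-7) with a warning; |r| > 1 is an error
clamp_r <- function(r, what = "correlation") {
  if (any(abs(r) > 1 + 1e-12)) stop(what, " outside [-1, 1]")
  hit <- abs(r) >= 1
  if (any(hit)) {
    warning(sum(hit), " ", what, " value(s) at |r| = 1 clamped to 1 - 1e-7")
    r[hit] <- sign(r[hit]) * (1 - 1e-7)
  }
  r
}

#' Fisher z-test for equality of two correlations
#'
#' Transforms each correlation with `atanh` and compares them on the normal
#' scale: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided standard-normal p-value. Vectorised over `r1`/`r2`.
#'
#' @param r1,r2 Correlations in the two conditions (|r| <= 1; values at
#'   exactly 1 are clamped with a warning).
#' @param n1,n2 Per-condition sample sizes (>= 4).
#' @return List with `z_stat` and `p_diff`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (any(c(n1, n2) < 4L)) stop("Fisher z-test needs n >= 4 in both conditions")
  r1 <- clamp_r(r1); r2 <- clamp_r(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (atanh(r1) - atanh(r2)) / se
  list(z_stat = z, p_diff = 2 * stats::pnorm(-abs(z)))
}

#' Two-sided p-value for a single Pearson correlation
#'
#' Uses `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param r Correlation(s), |r| <= 1.
#' @param n Sample size (>= 4).
#' @return P-value vector.
#' @export
correlation_p <- function(r, n) {
  if (any(n < 4L)) stop("need n >= 4")
  r <- clamp_r(r)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Empirical-Bayes local false discovery rate for z-statistics
#'
#' Estimates the marginal density of the z-values from a histogram (default
#' 120 bins spanning the data) smoothed by a log-linear natural-spline
#' Poisson fit, takes the standard normal as the theoretical null, estimates
#' the null proportion pi0 from the central half of the data, and reports
#' `lfdr(z) = pi0 * dnorm(z) / fhat(z)` capped at 1 (floored at 1e-300 so
#' hard zeros are never printed). An isotonic post-correction makes lfdr
#' monotone non-increasing in |z|. With fewer than 50 values, or a
#' degenerate density, the function falls back to Benjamini-Hochberg
#' q-values on the normal p-values (noted in the `"method"` attribute).
#'
#' @param z Numeric vector of z-statistics; fewer than 200 values triggers a
#'   stability warning.
#' @param n_bins Histogram bins (default 120).
#' @param df Spline basis dimension for the density fit (default 7).
#' @return Vector of lfdr values in `[1e-300, 1]`, with attributes
#'   `"pi0"` and `"method"` (`"lfdr"` or `"bh"`).
#' @export
local_fdr <- function(z, n_bins = 120L, df = 7L) {
  m <- length(z)
  bh_fallback <- function(reason) {
    message("local_fdr: ", reason, "; falling back to Benjamini-Hochberg q-values")
    q <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = "BH")
    structure(pmax(q, 1e-300), pi0 = NA_real_, method = "bh")
  }
  if (m < 50L) return(bh_fallback("fewer than 50 z-values"))
  if (m < 200L) {
    warning("local_fdr: fewer than 200 z-values; density estimate may be unstable")
  }
  rng <- range(z)
  if (diff(rng) < sqrt(.Machine$double.eps)) {
    return(bh_fallback("degenerate (near-constant) z distribution"))
  }
  pad <- diff(rng) * 1e-3
  breaks <- seq(rng[1L] - pad, rng[2L] + pad, length.out = n_bins + 1L)
  width <- breaks[2L] - breaks[1L]
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  cnt <- tabulate(findInterval(z, breaks, all.inside = TRUE), nbins = n_bins)
  basis <- splines::ns(mids, df = df)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, basis), cnt,
                                    family = stats::poisson(),
                                    control = stats::glm.control(maxit = 100L))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(bh_fallback("density fit did not converge"))
  }
  beta <- fit$coefficients
  fhat_at <- function(x) {
    B <- cbind(1, stats::predict(basis, x))
    pmax(as.vector(exp(B %*% beta)) / (m * width), 1e-300)
  }
  fz <- fhat_at(z)
  central <- z >= stats::quantile(z, 0.25) & z <= stats::quantile(z, 0.75)
  pi0 <- min(1, stats::median(fz[central] / stats::dnorm(z[central])))
  lfdr <- pmin(1, pmax(pi0 * stats::dnorm(z) / fz, 1e-300))
  # enforce monotone non-increasing lfdr in |z|
  ord <- order(abs(z))
  iso <- stats::isoreg(abs(z)[ord], -lfdr[ord])
  lfdr[ord] <- pmin(1, pmax(-iso$yf, 1e-300))
  structure(lfdr, pi0 = pi0, method = "lfdr")
}

#' Differential-correlation scan over all pairs of a gene set
#'
#' For every pair of `module_genes` the signed Pearson correlations in the
#' two condition matrices are compared with [fisher_z_test()]; local FDR is
#' estimated over the module's own z-statistics, Benjamini-Hochberg
#' q-values are reported alongside, and a pair is marked `switched` when its
#' correlations have opposite signs. Records are sorted by lfdr, then
#' descending |z|, then gene pair.
#'
#' @param cond1,cond2 Per-condition expression matrices
#'   ([split_by_condition()]).
#' @param module_genes Gene ids to scan (all must be rows of both matrices).
#' @return A `diffcorr_table` data frame with columns `gene_a, gene_b, r1,
#'   p1, r2, p2, z_stat, p_diff, q_bh, lfdr, switched` and attributes `n1`,
#'   `n2`, `pi0`, `lfdr_method`.
#' @export
diffcorr_scan <- function(cond1, cond2, module_genes = rownames(cond1)) {
  miss <- setdiff(module_genes, intersect(rownames(cond1), rownames(cond2)))
  if (length(miss)) {
    stop("gene(s) absent from a condition matrix: ", paste(miss, collapse = ", "))
  }
  x1 <- cond1[module_genes, , drop = FALSE]
  x2 <- cond2[module_genes, , drop = FALSE]
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  dead <- v1 == 0 | v2 == 0
  if (any(dead)) {
    warning("excluding ", sum(dead), " zero-variance gene(s): ",
            paste(module_genes[dead], collapse = ", "))
    module_genes <- module_genes[!dead]
    x1 <- x1[!dead, , drop = FALSE]; x2 <- x2[!dead, , drop = FALSE]
  }
  if (length(module_genes) < 2L) stop("need >= 2 usable genes")
  n1 <- ncol(x1); n2 <- ncol(x2)
  C1 <- stats::cor(t(x1)); C2 <- stats::cor(t(x2))
  ut <- which(upper.tri(C1), arr.ind = TRUE)
  # canonical within-pair order: gene_a < gene_b lexicographically
  ga <- module_genes[ut[, 1L]]; gb <- module_genes[ut[, 2L]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  r1 <- C1[ut]; r2 <- C2[ut]
  fz <- fisher_z_test(r1, n1, r2, n2)
  lfdr <- local_fdr(fz$z_stat)
  tab <- data.frame(
    gene_a = ga, gene_b = gb,
    r1 = r1, p1 = correlation_p(r1, n1),
    r2 = r2, p2 = correlation_p(r2, n2),
    z_stat = fz$z_stat, p_diff = fz$p_diff,
    q_bh = stats::p.adjust(fz$p_diff, method = "BH"),
    lfdr = as.vector(lfdr),
    switched = r1 * r2 < 0,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$lfdr, -abs(tab$z_stat), tab$gene_a, tab$gene_b), ]
  rownames(tab) <- NULL
  structure(tab, n1 = n1, n2 = n2,
            pi0 = attr(lfdr, "pi0"), lfdr_method = attr(lfdr, "method"),
            class = c("diffcorr_table", "data.frame"))
}

#' Significant sign-switching pairs
#'
#' Filters a differential-correlation table to pairs whose correlations have
#' opposite signs in the two conditions and whose local FDR is below the
#' cutoff (default 0.05).
#'
#' @param table A `diffcorr_table` ([diffcorr_scan()]).
#' @param lfdr_cut Local FDR threshold, default 0.05.
#' @return Subset of `table` rows.
#' @export
switched_pairs <- function(table, lfdr_cut = 0.05) {
  out <- table[table$switched & table$lfdr < lfdr_cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Eigen-molecule submodule network of a module
#'
#' Clusters the module's genes by average linkage on `1 - cor` (signed
#' Pearson), cuts into `n_submodules` groups, summarises each group by its
#' eigengene (a single-gene group by its standardised profile), and connects
#' submodules whose eigengene correlation exceeds `edge_threshold` in
#' absolute value.
#'
#' @param expr Expression matrix the clustering correlation is computed on.
#' @param module_genes Genes of the module.
#' @param n_submodules Number of submodules to cut into (>= 2).
#' @param edge_threshold Minimum |cor| for an edge (default 0.3).
#' @return List: `membership` (gene -> submodule label), `eigengenes`
#'   (samples x submodules), `edges` (data frame `a, b, weight`).
#' @export
eigen_molecule_network <- function(expr, module_genes, n_submodules,
                                   edge_threshold = 0.3) {
  if (n_submodules < 2L) stop("n_submodules must be >= 2")
  if (length(module_genes) < n_submodules) {
    stop("module smaller than the requested number of submodules")
  }
  sub <- expr[module_genes, , drop = FALSE]
  C <- stats::cor(t(sub))
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  cl <- stats::cutree(hc, k = n_submodules)
  labs <- sprintf("sub%02d", seq_len(n_submodules))
  membership <- stats::setNames(labs[cl], module_genes)
  E <- matrix(NA_real_, nrow = ncol(expr), ncol = n_submodules,
              dimnames = list(colnames(expr), labs))
  for (j in seq_len(n_submodules)) {
    members <- module_genes[cl == j]
    if (length(members) == 1L) {
      E[, j] <- as.vector(scale(expr[members, ]))
    } else {
      fake <- stats::setNames(rep(labs[j], length(members)), members)
      me <- module_eigengenes(expr[members, , drop = FALSE], fake)
      E[, j] <- me$eigengenes[, 1L]
    }
  }
  ce <- stats::cor(E)
  ut <- which(upper.tri(ce), arr.ind = TRUE)
  w <- ce[ut]
  keep <- abs(w) >= edge_threshold
  edges <- data.frame(a = labs[ut[keep, 1L]], b = labs[ut[keep, 2L]],
                      weight = w[keep], stringsAsFactors = FALSE)
  list(membership = membership, eigengenes = E, edges = edges)
}
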