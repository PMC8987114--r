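# Synthetic two-condition expression data with planted co-expression
# modules, trait-linked modules and planted sign-switching gene pairs.
#
# Single-factor model per module: gene g in module m is
#   x_g(s) = sqrt(rho) * f_m(s) + sqrt(1 - rho) * eps_g(s)
# so every pair inside a module has expected Pearson correlation rho
# (lambda^2 / (lambda^2 + sigma^2) with lambda = sqrt(rho), sigma^2 = 1 - rho).
# Trait-linked modules add delta (in factor-SD units) to f_m in case samples.
# Planted switch pairs load on pair-private factors, with the second gene's
# loading sign flipped in control samples only, giving expected within-pair
# correlation +rho in cases and -rho in controls while every pair not on the
# planted list stays null.

#' Simulate two-condition expression with planted structure
#'
#' Generates a gene-by-sample matrix from a per-module factor model, a 0/1
#' trait vector (1 = case, 0 = control) and the ground truth needed to score
#' module and switch-pair recovery. Defaults mirror a moderately sized
#' case-control microarray design: four 50-gene modules over a 300-gene
#' background, 150 case and 80 control samples, within-module correlation
#' 0.7, and two trait-linked modules with opposite effect directions.
#'
#' @param n_genes Total number of genes (modules plus background).
#' @param module_sizes Integer vector of planted module sizes.
#' @param rho Expected within-module (and within-switch-pair) Pearson
#'   correlation, in `[0, 1)`.
#' @param n_samples Length-2 integer vector: samples in condition 1 (case)
#'   and condition 2 (control).
#' @param trait_modules Indices of trait-linked modules.
#' @param trait_effects Mean shift of each trait-linked module's factor in
#'   case samples, in factor-SD units (recycled against `trait_modules`).
#' @param n_switch_pairs Number of planted sign-switching pairs.
#' @param switch_module Module whose genes host the switch pairs.
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return List with `expr` (matrix), `traits` (named 0/1 integer vector)
#'   and `truth` (a `dcc_truth` list: `module_of_gene` with 0 = background,
#'   `trait_modules`, `trait_effects`, `switch_pairs` data frame, `params`).
#' @export
simulate_expression <- function(n_genes = 300L,
                                module_sizes = rep(50L, 4L),
                                rho = 0.7,
                                n_samples = c(150L, 80L),
                                trait_modules = c(1L, 2L),
                                trait_effects = c(1, -1),
                                n_switch_pairs = 0L,
                                switch_module = 1L,
                                seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  module_sizes <- as.integer(module_sizes)
  if (any(module_sizes < 2L)) stop("every module needs >= 2 genes")
  if (sum(module_sizes) > n_genes) {
    stop("module sizes sum to ", sum(module_sizes), " > n_genes = ", n_genes)
  }
  if (length(n_samples) != 2L || any(n_samples < 4L)) {
    stop("n_samples must give >= 4 samples per condition")
  }
  if (length(trait_modules)) {
    trait_effects <- rep_len(trait_effects, length(trait_modules))
    if (any(trait_modules > length(module_sizes))) {
      stop("trait_modules index beyond the last module")
    }
  }
  n_switch_pairs <- as.integer(n_switch_pairs)
  if (n_switch_pairs > 0L) {
    if (switch_module > length(module_sizes)) stop("switch_module out of range")
    if (2L * n_switch_pairs > module_sizes[switch_module]) {
      stop("module ", switch_module, " too small for ", n_switch_pairs,
           " disjoint switch pairs")
    }
  }

  set.seed(as.integer(seed))
  n1 <- n_samples[1L]; n2 <- n_samples[2L]
  n <- n1 + n2
  traits <- c(rep(1L, n1), rep(0L, n2))
  sample_ids <- sprintf("S%03d", seq_len(n))
  names(traits) <- sample_ids
  gene_ids <- sprintf("G%04d", seq_len(n_genes))

  module_of_gene <- integer(n_genes)
  idx <- 0L
  for (m in seq_along(module_sizes)) {
    module_of_gene[idx + seq_len(module_sizes[m])] <- m
    idx <- idx + module_sizes[m]
  }
  names(module_of_gene) <- gene_ids

  lam <- sqrt(rho)
  sig <- sqrt(1 - rho)
  expr <- matrix(stats::rnorm(n_genes * n, sd = 1), nrow = n_genes,
                 dimnames = list(gene_ids, sample_ids))

  for (m in seq_along(module_sizes)) {
    f <- stats::rnorm(n)
    ti <- match(m, trait_modules)
    if (!is.na(ti)) f <- f + trait_effects[ti] * traits
    members <- which(module_of_gene == m)
    noise <- matrix(stats::rnorm(length(members) * n, sd = sig),
                    nrow = length(members))
    expr[members, ] <- lam * rep(f, each = length(members)) + noise
  }

  switch_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                             stringsAsFactors = FALSE)
  if (n_switch_pairs > 0L) {
    # last 2k genes of the host module; disjoint (a, b) pairs on private factors
    members <- which(module_of_gene == switch_module)
    pool <- utils::tail(members, 2L * n_switch_pairs)
    a_idx <- pool[seq_len(n_switch_pairs)]
    b_idx <- pool[n_switch_pairs + seq_len(n_switch_pairs)]
    flip <- ifelse(traits == 1L, 1, -1)  # sign of gene_b's loading per sample
    for (p in seq_len(n_switch_pairs)) {
      h <- stats::rnorm(n)
      expr[a_idx[p], ] <- lam * h + stats::rnorm(n, sd = sig)
      expr[b_idx[p], ] <- lam * flip * h + stats::rnorm(n, sd = sig)
    }
    switch_pairs <- data.frame(gene_a = gene_ids[a_idx],
                               gene_b = gene_ids[b_idx],
                               stringsAsFactors = FALSE)
  }

  truth <- structure(list(
    module_of_gene = module_of_gene,
    trait_modules = as.integer(trait_modules),
    trait_effects = if (length(trait_modules)) trait_effects else numeric(0),
    switch_pairs = switch_pairs,
    params = list(n_genes = n_genes, module_sizes = module_sizes, rho = rho,
                  n_samples = c(n1, n2), n_switch_pairs = n_switch_pairs,
                  switch_module = switch_module, seed = as.integer(seed))
  ), class = "dcc_truth")

  list(expr = expr, traits = traits, truth = truth)
}

#' Score module recovery against the planted partition
#'
#' Adjusted Rand index between the found module assignment (grey treated as
#' its own class) and the planted partition (background as its own class).
#'
#' @param found Named character vector gene -> module label, `"grey"` for
#'   unassigned genes (as returned by [detect_modules()]).
#' @param truth A `dcc_truth` object.
#' @return Adjusted Rand index in `[-1, 1]`.
#' @export
score_module_recovery <- function(found, truth) {
  stopifnot(inherits(truth, "dcc_truth"))
  planted <- truth$module_of_gene
  if (length(found) != length(planted) ||
      !setequal(names(found), names(planted))) {
    stop("gene universe of 'found' does not match the planted truth")
  }
  found <- found[names(planted)]
  mclust::adjustedRandIndex(as.character(found), as.character(planted))
}

#' Score recovery of planted sign-switching pairs
#'
#' A record is flagged when `switched` is true and its `lfdr` is below
#' `lfdr_cut`. Recall is the fraction of planted pairs flagged; empirical
#' FDR is the fraction of flagged pairs that were not planted (0 when
#' nothing is flagged).
#'
#' @param records Differential-correlation records ([diffcorr_scan()]).
#' @param truth A `dcc_truth` object with planted `switch_pairs`.
#' @param lfdr_cut Local FDR threshold, default 0.05.
#' @return List with `recall` and `empirical_fdr`.
#' @export
score_switch_recovery <- function(records, truth, lfdr_cut = 0.05) {
  stopifnot(inherits(truth, "dcc_truth"))
  planted <- truth$switch_pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  planted_keys <- key(planted$gene_a, planted$gene_b)
  flagged <- records[records$switched & records$lfdr < lfdr_cut, , drop = FALSE]
  flagged_keys <- unique(key(flagged$gene_a, flagged$gene_b))
  n_flag <- length(flagged_keys)
  hit <- sum(planted_keys %in% flagged_keys)
  list(
    recall = if (nrow(planted)) hit / nrow(planted) else NA_real_,
    empirical_fdr = if (n_flag) (n_flag - hit) / n_flag else 0
  )
}
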