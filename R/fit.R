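# The one-call model interface: fit the whole two-stage analysis
# (co-expression network + modules + trait association, then differential
# correlation within the key modules) and return a classed object.

#' Fit a differential-correlation co-expression network model
#'
#' Runs the full two-stage analysis on a gene-by-sample expression matrix
#' with a binary trait: (1) sample outlier removal, soft-threshold selection
#' (or a fixed power), adjacency, topological overlap, module detection on
#' TOM dissimilarity, module eigengenes and module-trait association;
#' (2) for the most positively and most negatively trait-correlated modules,
#' a Fisher-z differential-correlation scan between the two conditions with
#' local FDR control, sign-switch flagging and hub ranking; plus per-gene
#' differential expression.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @param traits Named 0/1 vector over the samples (1 = case, 0 = control).
#' @param power Soft-threshold exponent. The documented default is 5 (a
#'   typical choice for unsigned networks of this kind); `power = NULL`
#'   selects the power by scale-free fit via [pick_soft_threshold()].
#' @param candidate_powers Candidates for automatic selection.
#' @param target_r2 Scale-free fit target (default 0.80).
#' @param min_module_size Minimum module size (default 30).
#' @param cut_fraction Static tree-cut height as a fraction of the tallest
#'   merge (default 0.99).
#' @param sample_cut_quantile Merge-height quantile for sample outlier
#'   removal; 1 disables it.
#' @param lfdr_cut Local FDR threshold for switched pairs (default 0.05).
#' @param dge_alpha Adjusted-p cutoff for differential expression.
#' @param welch Use Welch's t-test for differential expression.
#' @param allow_single Tolerate a missing positive or negative key module.
#' @return An object of class `"dccnet"`; see [summary.dccnet()]. Components
#'   include `scale_free`, `modules`, `eigengenes`, `module_trait`,
#'   `key_modules`, `diffcorr` (one table per key module), `switched`,
#'   `hubs`, `dge`.
#' @seealso [simulate_expression()] to generate test data, [dcc_run()] to
#'   run the same analysis onto an output directory.
#' @export
#' @examples
#' sim <- simulate_expression(n_genes = 120, module_sizes = c(30, 30),
#'                            n_samples = c(30, 30), seed = 7)
#' fit <- dccnet(sim$expr, sim$traits, power = 5, min_module_size = 10)
#' print(fit)
dccnet <- function(expr, traits,
                   power = 5L, candidate_powers = 1:20, target_r2 = 0.80,
                   min_module_size = 30L, cut_fraction = 0.99,
                   sample_cut_quantile = 0.99,
                   lfdr_cut = 0.05, dge_alpha = 0.05, welch = FALSE,
                   allow_single = FALSE) {
  validate_expression(expr)
  traits <- traits[colnames(expr)]
  validate_traits(traits)

  sc <- cluster_samples(expr, cut_height_quantile = sample_cut_quantile)
  expr <- expr[, sc$kept, drop = FALSE]
  traits <- traits[sc$kept]
  validate_traits(traits)

  if (is.null(power)) {
    sf <- pick_soft_threshold(expr, candidate_powers, target_r2)
  } else {
    sf <- structure(list(power = as.integer(power), r_squared = NA_real_,
                         slope = NA_real_, mean_connectivity = NA_real_,
                         fits = NULL), class = "scale_free_fit")
  }

  S <- correlation_matrix(expr, unsigned = TRUE)
  A <- adjacency(S, sf$power)
  TOM <- tom(A)
  det <- detect_modules(dist_tom(TOM), min_module_size = min_module_size,
                        cut_fraction = cut_fraction)
  modules <- det$modules

  me <- module_eigengenes(expr, modules)
  mt <- module_trait(me, traits)
  gsmm <- gene_significance_mm(expr, traits, me, modules)
  key <- select_key_modules(mt, allow_single = allow_single)

  split <- split_by_condition(expr, traits)
  diffcorr <- list()
  switched <- list()
  for (lab in stats::na.omit(unlist(key))) {
    members <- names(modules)[modules == lab]
    tab <- diffcorr_scan(split$cond1, split$cond2, members)
    diffcorr[[lab]] <- tab
    switched[[lab]] <- switched_pairs(tab, lfdr_cut)
  }
  all_switched <- do.call(rbind, c(switched, list(make.row.names = FALSE)))
  hubs <- rank_hubs(all_switched)
  dge <- differential_expression(split$cond1, split$cond2, welch = welch,
                                 alpha = dge_alpha)

  structure(list(
    expr = expr, traits = traits,
    samples_removed = sc$removed, sample_dendrogram = sc$dendrogram,
    scale_free = sf, modules = modules, gene_dendrogram = det$dendrogram,
    eigengenes = me, module_trait = mt, gs_mm = gsmm,
    key_modules = key, diffcorr = diffcorr, switched = switched,
    hubs = hubs, dge = dge,
    params = list(power = sf$power, target_r2 = target_r2,
                  min_module_size = min_module_size,
                  cut_fraction = cut_fraction,
                  sample_cut_quantile = sample_cut_quantile,
                  lfdr_cut = lfdr_cut, dge_alpha = dge_alpha, welch = welch)
  ), class = "dccnet")
}

#' @export
print.dccnet <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$modules), "grey"))
  n_sw <- sum(vapply(x$switched, nrow, 0L))
  cat("Differential-correlation co-expression network fit\n")
  cat(sprintf("  %d genes x %d samples (%d case / %d control, %d outlier(s) removed)\n",
              nrow(x$expr), ncol(x$expr), sum(x$traits == 1L),
              sum(x$traits == 0L), length(x$samples_removed)))
  cat(sprintf("  soft-threshold power %d%s; %d module(s), %d grey gene(s)\n",
              x$scale_free$power,
              if (is.na(x$scale_free$r_squared)) "" else
                sprintf(" (scale-free R^2 = %.2f)", x$scale_free$r_squared),
              n_mod, sum(x$modules == "grey")))
  cat(sprintf("  key modules: positive = %s, negative = %s\n",
              x$key_modules$positive, x$key_modules$negative))
  cat(sprintf("  %d sign-switching pair(s) at lfdr < %.3g; %d DE gene(s) at adj. p < %.3g\n",
              n_sw, x$params$lfdr_cut, sum(x$dge$significant),
              x$params$dge_alpha))
  invisible(x)
}

#' Summarise a fitted dccnet model
#'
#' @param object A `dccnet` fit.
#' @param ... Unused.
#' @return Invisibly, a list with the module-trait table, per-module
#'   switched-pair counts and the top hub genes; also printed.
#' @export
summary.dccnet <- function(object, ...) {
  print(object)
  mt <- object$module_trait[order(-abs(object$module_trait$r)), ]
  cat("\nModule-trait associations:\n")
  print(format(mt, digits = 3), row.names = FALSE)
  sw <- vapply(object$switched, nrow, 0L)
  if (length(sw)) {
    cat("\nSwitched pairs per key module:\n")
    for (lab in names(sw)) cat(sprintf("  %s: %d\n", lab, sw[lab]))
  }
  if (nrow(object$hubs)) {
    cat("\nTop hub genes (switched-pair network):\n")
    print(format(utils::head(object$hubs, 10L), digits = 3), row.names = FALSE)
  }
  invisible(list(module_trait = mt, switched_counts = sw, hubs = object$hubs))
}

#' Plot a fitted dccnet model
#'
#' Two panels: the gene dendrogram used for module detection, and a bar plot
#' of module-trait correlations (key modules highlighted).
#'
#' @param x A `dccnet` fit.
#' @param ... Passed to `plot.hclust` for the dendrogram panel.
#' @export
plot.dccnet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(5, 4, 3, 1))
  on.exit(graphics::par(op))
  plot(x$gene_dendrogram, labels = FALSE, hang = -1,
       main = "Gene clustering (1 - TOM)", xlab = "", sub = "", ...)
  mt <- x$module_trait[order(x$module_trait$r), ]
  cols <- ifelse(mt$module %in% unlist(x$key_modules), mt$module, "grey80")
  graphics::barplot(mt$r, names.arg = mt$module, col = cols, las = 2,
                    ylab = "eigengene-trait correlation",
                    main = "Module-trait association")
  graphics::abline(h = 0)
  invisible(x)
}
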