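# Module detection on TOM dissimilarity, module eigengenes, module-trait
# association, gene significance / module membership, and selection of the
# key positively and negatively trait-correlated modules.

# WGCNA-style colour sequence for module labels, by descending module size
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

#' Cluster samples and drop outliers
#'
#' Samples are clustered by average-linkage on the Euclidean distance of
#' per-gene standardised expression. The tree is cut an outlier fence of
#' 3 interquartile ranges above the `cut_height_quantile` quantile of the
#' merge heights, so an unbroken tree is left intact and only merges far
#' above the bulk are severed; the largest resulting cluster is kept. With
#' `cut_height_quantile = 1` all samples are retained.
#'
#' @param expr Expression matrix, genes in rows.
#' @param cut_height_quantile Quantile of merge heights anchoring the cut
#'   (default 0.99).
#' @return List: `dendrogram` (an `hclust`), `kept` and `removed` sample ids.
#' @export
cluster_samples <- function(expr, cut_height_quantile = 0.99) {
  validate_expression(expr)
  if (ncol(expr) < 4L) stop("need >= 4 samples to screen for outliers")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) ignored for sample clustering")
    expr <- expr[v > 0, , drop = FALSE]
  }
  Z <- t(scale(t(expr)))
  hc <- stats::hclust(stats::dist(t(Z)), method = "average")
  h <- stats::quantile(hc$height, probs = min(cut_height_quantile, 1),
                       names = FALSE) + 3 * stats::IQR(hc$height)
  if (h >= max(hc$height)) {
    return(list(dendrogram = hc, kept = colnames(expr), removed = character(0)))
  }
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[which.max(sizes)])
  kept <- colnames(expr)[cl == big]
  if (length(kept) < 4L) {
    stop("largest sample cluster has fewer than 4 samples; data too fragmented")
  }
  removed <- setdiff(colnames(expr), kept)
  if (length(removed)) {
    message("removing ", length(removed), " outlier sample(s): ",
            paste(removed, collapse = ", "))
  }
  list(dendrogram = hc, kept = kept, removed = removed)
}

#' Detect co-expression modules on TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of the genes followed by a static
#' cut at `cut_fraction` times the maximum merge height. Clusters smaller
#' than `min_module_size` are set to grey; a single reassignment pass then
#' lets each grey gene join the module with the smallest mean dissimilarity
#' to its members, provided that mean is below `reassign_threshold`.
#' Surviving modules are labelled by colour in descending size order
#' (equal sizes ordered by their lexicographically smallest member id).
#'
#' @param dist_mat TOM dissimilarity ([dist_tom()]).
#' @param min_module_size Smallest allowed module (default 30).
#' @param cut_fraction Static cut height as a fraction of the tallest merge
#'   (default 0.99).
#' @param reassign_threshold Mean-dissimilarity ceiling for rescuing grey
#'   genes (default 0.85).
#' @return List: `dendrogram` (`hclust`) and `modules` (named character
#'   vector gene -> colour, `"grey"` for unassigned).
#' @export
detect_modules <- function(dist_mat, min_module_size = 30L,
                           cut_fraction = 0.99, reassign_threshold = 0.85) {
  if (min_module_size < 2L) stop("min_module_size must be >= 2")
  genes <- rownames(dist_mat)
  hc <- stats::hclust(stats::as.dist(dist_mat), method = "average")
  cl <- stats::cutree(hc, h = cut_fraction * max(hc$height))
  names(cl) <- genes
  sizes <- table(cl)
  keep_ids <- as.integer(names(sizes)[sizes >= min_module_size])
  grey <- !cl %in% keep_ids

  if (all(grey)) {
    warning("all genes unassigned (grey); no module met the minimum size")
    modules <- stats::setNames(rep("grey", length(genes)), genes)
    return(list(dendrogram = hc, modules = modules))
  }

  # one-pass rescue of grey genes into the nearest module
  if (any(grey)) {
    member_idx <- lapply(keep_ids, function(id) which(cl == id & !grey))
    for (g in which(grey)) {
      md <- vapply(member_idx, function(ix) mean(dist_mat[g, ix]), 0)
      best <- which.min(md)
      if (md[best] < reassign_threshold) cl[g] <- keep_ids[best]
    }
    grey <- !cl %in% keep_ids
  }

  # size-ordered colour labels; ties broken by smallest member gene id
  tab <- table(cl[!grey])
  ids <- as.integer(names(tab))
  first_gene <- vapply(ids, function(id) min(genes[cl == id]), "")
  ord <- order(-as.integer(tab), first_gene)
  lab <- character(max(ids))
  for (j in seq_along(ord)) {
    id <- ids[ord[j]]
    lab[id] <- if (j <= length(module_colors)) module_colors[j] else
      paste0("module", j)
  }
  modules <- ifelse(grey, "grey", lab[cl])
  names(modules) <- genes
  list(dendrogram = hc, modules = modules)
}

#' Module eigengenes
#'
#' Per module, each member gene is standardised across samples and the first
#' right singular vector over samples (the first principal component) is
#' taken as the module eigengene. Eigengenes have unit norm and are
#' sign-fixed so their correlation with the module's mean expression profile
#' is non-negative. Zero-variance genes are dropped with a warning.
#'
#' @param expr Expression matrix, genes in rows.
#' @param modules Named gene -> colour vector ([detect_modules()]).
#' @return A `module_eigengenes` list: `eigengenes` (samples x modules
#'   matrix), `var_explained`, `sizes`.
#' @export
module_eigengenes <- function(expr, modules) {
  modules <- modules[rownames(expr)]
  labs <- setdiff(unique(modules), "grey")
  if (!length(labs)) stop("no non-grey module to summarise")
  E <- matrix(NA_real_, nrow = ncol(expr), ncol = length(labs),
              dimnames = list(colnames(expr), labs))
  ve <- stats::setNames(numeric(length(labs)), labs)
  sizes <- stats::setNames(integer(length(labs)), labs)
  for (lab in labs) {
    members <- names(modules)[modules == lab]
    sub <- expr[members, , drop = FALSE]
    v <- apply(sub, 1L, stats::var)
    if (any(v == 0)) {
      warning("module ", lab, ": dropping ", sum(v == 0), " zero-variance gene(s)")
      sub <- sub[v > 0, , drop = FALSE]
    }
    if (nrow(sub) < 2L) stop("module ", lab, " has < 2 usable genes")
    Z <- t(scale(t(sub)))             # genes standardised across samples
    sv <- svd(t(Z), nu = 1L, nv = 0L) # samples x genes
    e <- sv$u[, 1L]
    mp <- colMeans(Z)                 # module mean profile over samples
    if (stats::sd(mp) > 0 && stats::cor(e, mp) < 0) e <- -e
    E[, lab] <- e
    ve[lab] <- sv$d[1L]^2 / sum(sv$d^2)
    sizes[lab] <- length(members)
  }
  structure(list(eigengenes = E, var_explained = ve, sizes = sizes),
            class = "module_eigengenes")
}

#' Module-trait association table
#'
#' Pearson (point-biserial) correlation of each module eigengene with the
#' 0/1 trait, with the usual t-based two-sided p-value on `n - 2` degrees of
#' freedom.
#'
#' @param me Module eigengenes ([module_eigengenes()]).
#' @param traits Named 0/1 trait vector aligned to the eigengene samples.
#' @return Data frame: `module`, `r`, `p`, `n`, `size`.
#' @export
module_trait <- function(me, traits) {
  stopifnot(inherits(me, "module_eigengenes"))
  traits <- traits[rownames(me$eigengenes)]
  if (anyNA(traits)) stop("traits missing for some eigengene samples")
  if (stats::var(traits) == 0) stop("trait is constant; association undefined")
  n <- length(traits)
  r <- as.vector(stats::cor(me$eigengenes, traits))
  p <- cor_test_p(r, n)
  data.frame(module = colnames(me$eigengenes), r = r, p = p, n = n,
             size = as.integer(me$sizes[colnames(me$eigengenes)]),
             stringsAsFactors = FALSE)
}

# two-sided p for a Pearson correlation via t = r sqrt((n-2)/(1-r^2))
cor_test_p <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Gene significance and module membership
#'
#' GS is the correlation of a gene's expression with the trait; MM the
#' correlation with its own module's eigengene. Absolute values by default
#' (`signed = TRUE` keeps signs). Also reports, per module, the correlation
#' of GS with MM over member genes.
#'
#' @param expr Expression matrix, genes in rows.
#' @param traits Named 0/1 trait vector.
#' @param me Module eigengenes.
#' @param modules Gene -> colour assignment.
#' @param signed Keep correlation signs (default `FALSE`).
#' @return List: `gs` (per gene), `mm` (per gene, `NA` for grey genes),
#'   `gs_mm_cor` (per module).
#' @export
gene_significance_mm <- function(expr, traits, me, modules, signed = FALSE) {
  traits <- traits[colnames(expr)]
  modules <- modules[rownames(expr)]
  gs <- as.vector(stats::cor(t(expr), traits))
  names(gs) <- rownames(expr)
  mm <- stats::setNames(rep(NA_real_, nrow(expr)), rownames(expr))
  for (lab in colnames(me$eigengenes)) {
    members <- names(modules)[modules == lab]
    members <- intersect(members, rownames(expr))
    if (length(members)) {
      mm[members] <- as.vector(stats::cor(t(expr[members, , drop = FALSE]),
                                          me$eigengenes[, lab]))
    }
  }
  if (!signed) {
    gs <- abs(gs)
    mm <- abs(mm)
  }
  gs_mm <- vapply(colnames(me$eigengenes), function(lab) {
    members <- names(modules)[modules == lab]
    members <- members[!is.na(mm[members])]
    if (length(members) < 3L) return(NA_real_)
    stats::cor(gs[members], mm[members])
  }, 0)
  list(gs = gs, mm = mm, gs_mm_cor = gs_mm)
}

#' Select the key positively and negatively trait-correlated modules
#'
#' Returns the module with the largest positive and the module with the most
#' negative trait correlation, each required to be significant at `alpha`.
#' Ties are broken by larger module size, then label order.
#'
#' @param mt Module-trait table ([module_trait()]).
#' @param alpha Significance level (default 0.05).
#' @param allow_single Allow one slot to be `NA` when no module qualifies
#'   for it (default `FALSE`, which raises an error instead).
#' @return List with `positive` and `negative` module labels.
#' @export
select_key_modules <- function(mt, alpha = 0.05, allow_single = FALSE) {
  mt <- mt[is.finite(mt$r), , drop = FALSE]
  if (nrow(mt) < 1L) stop("no module with a finite trait correlation")
  pick <- function(df) {
    if (!nrow(df)) return(NA_character_)
    df <- df[order(-abs(df$r), -df$size, df$module), , drop = FALSE]
    df$module[1L]
  }
  pos <- pick(mt[mt$r > 0 & mt$p < alpha, , drop = FALSE])
  neg <- pick(mt[mt$r < 0 & mt$p < alpha, , drop = FALSE])
  if ((is.na(pos) || is.na(neg)) && !allow_single) {
    stop("no significant ", if (is.na(pos)) "positively" else "negatively",
         "-correlated module at alpha = ", alpha,
         "; review thresholds or set allow_single = TRUE")
  }
  if (is.na(pos) && is.na(neg)) {
    stop("no module significantly associated with the trait at alpha = ", alpha)
  }
  list(positive = pos, negative = neg)
}
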