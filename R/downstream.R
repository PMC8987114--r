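# Downstream analyses: two-sample differential expression with
# Benjamini-Hochberg adjustment, hypergeometric gene-set enrichment, and
# hub-gene ranking on the switched-pair network.

#' Two-sample differential expression
#'
#' Per-gene two-sample t-test between the condition matrices
#' (pooled-variance Student's t by default, Welch optional), two-sided
#' p-values, Benjamini-Hochberg adjustment over all tested genes, and a
#' significance flag at `alpha`.
#'
#' @param cond1,cond2 Per-condition expression matrices with identical gene
#'   rows ([split_by_condition()]).
#' @param welch Use the Welch (unequal-variance) test (default `FALSE`).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return Data frame: `gene, mean_cond1, mean_cond2, t, df, p, p_adj,
#'   significant`.
#' @export
differential_expression <- function(cond1, cond2, welch = FALSE, alpha = 0.05) {
  if (!identical(rownames(cond1), rownames(cond2))) {
    stop("condition matrices must share the same gene rows in the same order")
  }
  n1 <- ncol(cond1); n2 <- ncol(cond2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per condition")
  m1 <- rowMeans(cond1); m2 <- rowMeans(cond2)
  v1 <- rowSums((cond1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((cond2 - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df = df)
  zero_var <- se2 == 0
  if (any(zero_var)) {
    same <- zero_var & m1 == m2
    diff_ <- zero_var & m1 != m2
    p[same] <- 1; t[same] <- 0
    if (any(diff_)) {
      warning(sum(diff_), " gene(s) with zero variance but unequal means; p floored at 1e-300")
      p[diff_] <- 1e-300
      t[diff_] <- sign(m1[diff_] - m2[diff_]) * Inf
    }
  }
  p_adj <- benjamini_hochberg(p)
  data.frame(gene = rownames(cond1), mean_cond1 = m1, mean_cond2 = m2,
             t = t, df = df, p = p, p_adj = p_adj,
             significant = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment; input order preserved.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each gene set for over-representation in the query via the
#' upper-tail hypergeometric probability `P(X >= k)` (overlap `k`, set size
#' `K`, query size `n`, universe size `N`), with Benjamini-Hochberg
#' adjustment across sets. Sets are intersected with the universe before
#' testing; a set with no overlap keeps `p = 1`.
#'
#' @param query Gene ids of interest (must be a subset of `universe`).
#' @param universe Background gene ids.
#' @param sets Named list of gene sets ([read_gmt()]).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return Data frame: `set, overlap, set_size, query_size, universe_size,
#'   p, p_adj, significant`.
#' @export
enrich <- function(query, universe, sets, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe) || !length(query)) stop("empty query or universe")
  out <- setdiff(query, universe)
  if (length(out)) {
    stop("query gene(s) outside the universe: ", paste(out, collapse = ", "))
  }
  N <- length(universe); n <- length(query)
  K <- vapply(sets, function(s) length(intersect(s, universe)), 0L)
  k <- vapply(sets, function(s) length(intersect(intersect(s, universe), query)), 0L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- benjamini_hochberg(p)
  data.frame(set = names(sets), overlap = k, set_size = K,
             query_size = n, universe_size = N,
             p = p, p_adj = p_adj, significant = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank hub genes in the switched-pair network
#'
#' Counts each gene's degree over the unique significant switched pairs.
#' Ties are broken by the sum of |r1 - r2| over a gene's incident edges
#' (rewarding stronger correlation reversals), then by gene id.
#'
#' @param records Switched-pair records ([switched_pairs()]).
#' @return Data frame sorted by rank: `gene, degree, reversal_strength,
#'   rank`.
#' @export
rank_hubs <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(data.frame(gene = character(0), degree = integer(0),
                      reversal_strength = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(records$gene_a, records$gene_b)
  b <- pmax(records$gene_a, records$gene_b)
  keep <- !duplicated(paste(a, b, sep = "|"))
  a <- a[keep]; b <- b[keep]
  w <- abs(records$r1 - records$r2)[keep]
  genes <- sort(unique(c(a, b)))
  deg <- stats::setNames(integer(length(genes)), genes)
  sw <- stats::setNames(numeric(length(genes)), genes)
  for (i in seq_along(a)) {
    deg[a[i]] <- deg[a[i]] + 1L; deg[b[i]] <- deg[b[i]] + 1L
    sw[a[i]] <- sw[a[i]] + w[i]; sw[b[i]] <- sw[b[i]] + w[i]
  }
  ord <- order(-deg, -sw, genes)
  data.frame(gene = genes[ord], degree = as.integer(deg[ord]),
             reversal_strength = sw[ord], rank = seq_along(genes),
             row.names = NULL, stringsAsFactors = FALSE)
}
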