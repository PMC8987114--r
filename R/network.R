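# Weighted co-expression network construction: Pearson correlation,
# soft-thresholded adjacency, scale-free power selection, topological
# overlap and its dissimilarity.

#' Gene-gene Pearson correlation matrix
#'
#' The unsigned variant (default, used for network construction) stores
#' absolute correlations; the signed variant keeps the sign and is what the
#' differential-correlation stage works with.
#'
#' @param expr Expression matrix, genes in rows.
#' @param unsigned Take absolute values (default `TRUE`).
#' @return Symmetric matrix with unit diagonal and an `"unsigned"` attribute.
#' @export
correlation_matrix <- function(expr, unsigned = TRUE) {
  validate_expression(expr)
  if (ncol(expr) < 3L) stop("need >= 3 samples for a usable correlation matrix")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(rownames(expr)[v == 0], collapse = ", "),
         "; filter before computing correlations")
  }
  S <- stats::cor(t(expr))
  if (unsigned) S <- abs(S)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  attr(S, "unsigned") <- unsigned
  S
}

#' Soft-thresholded adjacency
#'
#' Raises every entry of an unsigned correlation matrix to the power `beta`,
#' emphasising strong correlations while keeping the network weighted.
#'
#' @param S Unsigned correlation matrix ([correlation_matrix()]).
#' @param power Positive integer soft-threshold exponent.
#' @return Adjacency matrix in `[0, 1]` with unit diagonal and a `"power"`
#'   attribute.
#' @export
adjacency <- function(S, power) {
  if (length(power) != 1L || power < 1 || power != round(power)) {
    stop("power must be a positive integer")
  }
  if (min(S) < 0 || isFALSE(attr(S, "unsigned"))) {
    stop("adjacency requires an unsigned correlation matrix (entries in [0, 1])")
  }
  A <- S^power
  diag(A) <- 1
  attr(A, "power") <- as.integer(power)
  attr(A, "unsigned") <- NULL
  A
}

#' Select a soft-threshold power for scale-free topology
#'
#' For each candidate power the whole-network connectivity
#' `k_i = sum_{j != i} a_ij` is computed, genes are binned into 10
#' equal-count bins of `k`, and `log10` of the per-unit-`k` density of each
#' bin is regressed on `log10` of the bin's mean connectivity. A good
#' scale-free fit is a high R-squared with a negative slope. Powers that
#' collapse the network (mean connectivity below `min_mean_k`) are not
#' eligible: once nearly every `k` is 0 the log-log fit turns spuriously
#' linear and stops measuring topology. The smallest eligible power reaching
#' `target_r2` is returned; if none does, the best-fitting eligible power is
#' returned with a warning.
#'
#' @param expr Expression matrix, genes in rows.
#' @param candidate_powers Ascending integer candidates (default 1..20).
#' @param target_r2 Required scale-free fit R-squared (default 0.80).
#' @param n_bins Connectivity bins used in the fit.
#' @param min_mean_k Smallest mean connectivity at which a candidate power
#'   is still considered (default 1).
#' @return A `scale_free_fit` list: `power`, `r_squared`, `slope`,
#'   `mean_connectivity`, and a per-candidate `fits` data frame.
#' @export
pick_soft_threshold <- function(expr, candidate_powers = 1:20,
                                target_r2 = 0.80, n_bins = 10L,
                                min_mean_k = 1) {
  S <- correlation_matrix(expr, unsigned = TRUE)
  fits <- data.frame(power = as.integer(candidate_powers), r_squared = NA_real_,
                     slope = NA_real_, mean_connectivity = NA_real_)
  for (i in seq_along(candidate_powers)) {
    A <- adjacency(S, candidate_powers[i])
    k <- rowSums(A) - 1
    f <- scale_free_r2(k, n_bins = n_bins)
    fits$r_squared[i] <- f$r_squared
    fits$slope[i] <- f$slope
    fits$mean_connectivity[i] <- mean(k)
  }
  eligible <- fits$mean_connectivity >= min_mean_k
  if (!any(eligible)) eligible <- rep(TRUE, nrow(fits))
  ok <- eligible & !is.na(fits$slope) & fits$slope < 0
  hit <- which(ok & fits$r_squared >= target_r2)
  if (length(hit)) {
    sel <- hit[1L]
  } else {
    pool <- if (any(ok)) which(ok) else which(eligible)
    sel <- pool[which.max(fits$r_squared[pool])]
    warning(sprintf(
      "no candidate power reached scale-free R^2 >= %.2f; returning power %d (R^2 = %.3f)",
      target_r2, fits$power[sel], fits$r_squared[sel]))
  }
  structure(list(power = fits$power[sel],
                 r_squared = fits$r_squared[sel],
                 slope = fits$slope[sel],
                 mean_connectivity = fits$mean_connectivity[sel],
                 fits = fits),
            class = "scale_free_fit")
}

# log10 density of connectivity vs log10 mean connectivity over equal-count
# bins; returns plain R^2 and the slope of the linear fit
scale_free_r2 <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 10L) {
    stop("fewer than 10 genes with positive connectivity; too small to assess topology")
  }
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE))
  if (length(br) < 4L) return(list(r_squared = NA_real_, slope = NA_real_))
  cuts <- cut(k, breaks = br, include.lowest = TRUE)
  cnt <- tabulate(cuts, nbins = nlevels(cuts))
  width <- diff(br)
  dens <- cnt / (length(k) * width)
  km <- tapply(k, cuts, mean)
  keep <- cnt > 0 & km > 0 & dens > 0
  if (sum(keep) < 3L) return(list(r_squared = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(dens[keep]) ~ log10(km[keep]))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]))
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("Scale-free fit: power = %d, R^2 = %.3f, slope = %.3f, mean k = %.2f\n",
              x$power, x$r_squared, x$slope, x$mean_connectivity))
  invisible(x)
}

#' Topological overlap matrix
#'
#' Converts an adjacency matrix into the unsigned topological overlap
#' matrix,
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
#'       \quad l_{ij} = \sum_{u \ne i,j} a_{iu} a_{ju},}
#' with connectivity `k_i = sum_{j != i} a_ij` (self-adjacency excluded). An
#' isolated gene has a zero TOM row; a clique with unit adjacency has TOM 1
#' everywhere. The diagonal is fixed to 1 by convention.
#'
#' @param adj Adjacency matrix ([adjacency()]).
#' @param block_size Optional number of columns per multiplication block;
#'   results are independent of it (it only bounds memory).
#' @return Symmetric TOM matrix with entries in `[0, 1]`.
#' @export
tom <- function(adj, block_size = NULL) {
  n <- nrow(adj)
  if (is.null(block_size) || block_size >= n) {
    AA <- adj %*% adj
  } else {
    AA <- matrix(0, n, n, dimnames = dimnames(adj))
    starts <- seq(1L, n, by = as.integer(block_size))
    for (s in starts) {
      cols <- s:min(s + block_size - 1L, n)
      AA[, cols] <- adj %*% adj[, cols, drop = FALSE]
    }
  }
  # with unit diagonal, the u = i and u = j terms of (A %*% A)_ij are both a_ij
  L <- AA - 2 * adj
  k <- rowSums(adj) - 1
  kmin <- outer(k, k, pmin)
  TOM <- (L + adj) / (kmin + 1 - adj)
  TOM <- (TOM + t(TOM)) / 2
  TOM[TOM < 0] <- 0          # guard against rounding just below zero
  TOM[TOM > 1] <- 1
  diag(TOM) <- 1
  TOM
}

#' TOM dissimilarity
#'
#' `1 - TOM`, the distance used for gene clustering; the diagonal is 0.
#'
#' @param tom_mat TOM matrix ([tom()]).
#' @return Dissimilarity matrix.
#' @export
dist_tom <- function(tom_mat) {
  D <- 1 - tom_mat
  diag(D) <- 0
  D
}
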