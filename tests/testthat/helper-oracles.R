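# Independent brute-force oracles used to check the vectorised
# implementations on small inputs.

# Eq.-by-eq triple-loop topological overlap
tom_bruteforce <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - 1
  T <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[j, u]
    T[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(T) <- dimnames(A)
  T
}

# textbook Pearson correlation of two vectors
pearson_bruteforce <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# quadratic step-up Benjamini-Hochberg from the definition:
# adj_i = min over j with p_(j) >= p_(i) of m * p_(j) / j, capped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper-tail hypergeometric P(X >= k) by direct summation of choose() terms
hyper_tail_bruteforce <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# random symmetric adjacency with unit diagonal, entries in [0, 1]
random_adjacency <- function(n) {
  A <- matrix(stats::runif(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  A
}

# paired samples with a given common correlation in both conditions,
# rowwise; returns the two per-condition sample correlations per pair
null_pair_correlations <- function(m, n1, n2, rho) {
  rowcor <- function(a, b) {
    a <- a - rowMeans(a); b <- b - rowMeans(b)
    rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
  }
  gen <- function(n) {
    f <- matrix(stats::rnorm(m * n), m)
    e <- matrix(stats::rnorm(m * n), m)
    list(x = f, y = rho * f + sqrt(1 - rho^2) * e)
  }
  c1 <- gen(n1); c2 <- gen(n2)
  list(r1 = rowcor(c1$x, c1$y), r2 = rowcor(c2$x, c2$y))
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
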