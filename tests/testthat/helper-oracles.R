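# Independent brute-force references used to check the package's
# implementations. These deliberately use the most literal formulation
# possible (queues, double loops, direct formulas), not the code under test.

# scalar breadth-first flood fill with |HU - HU(seed)| <= tol
brute_flood_fill <- function(arr, seed, tol, connectivity = 6) {
  d <- dim(arr)
  offs <- if (connectivity == 26) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
           ncol = 3, byrow = TRUE)
  }
  hv <- arr[seed[1], seed[2], seed[3]]
  out <- array(FALSE, d)
  out[seed[1], seed[2], seed[3]] <- TRUE
  queue <- list(seed)
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (any(q < 1) || any(q > d)) next
      if (out[q[1], q[2], q[3]]) next
      if (abs(arr[q[1], q[2], q[3]] - hv) <= tol) {
        out[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  out
}

brute_pearson <- function(x, y) {
  n <- length(x)
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mean(x)) * (y[i] - mean(y))
    dx2 <- dx2 + (x[i] - mean(x))^2
    dy2 <- dy2 + (y[i] - mean(y))^2
  }
  num / sqrt(dx2 * dy2)
}

brute_ccc <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# AUC by explicit enumeration of all positive/negative pairs, ties = 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

brute_icc <- function(values, cluster) {
  cluster <- as.factor(cluster)
  a <- nlevels(cluster); N <- length(values)
  ni <- as.numeric(table(cluster))
  mi <- tapply(values, cluster, mean)
  msb <- sum(ni * (mi - mean(values))^2) / (a - 1)
  ssw <- 0
  for (i in seq_len(N)) ssw <- ssw + (values[i] - mi[cluster[i]])^2
  msw <- ssw / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)
  unname((msb - msw) / (msb + (k0 - 1) * msw))
}

random_pairs <- function(n) {
  data.frame(ref_perfusion = runif(n, 0.3, 3.5),
             ct_perfusion = runif(n, 0.3, 3.5))
}
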