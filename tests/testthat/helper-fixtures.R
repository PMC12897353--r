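# Small in-code fixtures and independent oracles shared across test files.

random_expr <- function(y, s, seed = 1, max_val = 10) {
  set.seed(seed)
  expression_matrix(matrix(round(runif(y * s, 0, max_val), 3), y, s))
}

# two tight, well-separated groups with distinct expression profiles
# (separation visible to euclidean, correlation and cosine metrics alike)
two_blob_matrix <- function(n_per = 5, s = 6, sep = 20, seed = 1) {
  set.seed(seed)
  prof_a <- c(rep(sep, ceiling(s / 2)), rep(1, floor(s / 2)))
  prof_b <- rev(prof_a)
  noise <- function(n) matrix(rlnorm(n * s, 0, 0.1), n, s)
  expression_matrix(rbind(noise(n_per) * rep(prof_a, each = n_per),
                          noise(n_per) * rep(prof_b, each = n_per)))
}

# exhaustive pair-counting ARI, straight from the contingency definition
oracle_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  n11 <- sum(same_a[up] & same_b[up])
  n00 <- sum(!same_a[up] & !same_b[up])
  n10 <- sum(same_a[up] & !same_b[up])
  n01 <- sum(!same_a[up] & same_b[up])
  total <- choose(n, 2)
  index <- n11
  exp_index <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == exp_index) return(0)
  (index - exp_index) / (max_index - exp_index)
}

# NMI from raw entropy sums (arithmetic normalization)
oracle_nmi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0) mi <- mi + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  ha <- ent(rowSums(tab) / n); hb <- ent(colSums(tab) / n)
  if ((ha + hb) == 0) return(1)
  mi / ((ha + hb) / 2)
}

# silhouette by literal definition, point by point
oracle_silhouette <- function(x, cl) {
  d <- as.matrix(dist(x))
  mean(sapply(seq_len(nrow(x)), function(i) {
    own <- cl[i]
    mates <- setdiff(which(cl == own), i)
    if (length(mates) == 0) return(0)
    a <- mean(d[i, mates])
    b <- min(sapply(setdiff(unique(cl), own), function(g) mean(d[i, cl == g])))
    (b - a) / max(a, b)
  }))
}

oracle_dbi <- function(x, cl) {
  ks <- sort(unique(cl))
  cent <- t(sapply(ks, function(g) colMeans(x[cl == g, , drop = FALSE])))
  s <- sapply(seq_along(ks), function(gi) {
    pts <- x[cl == ks[gi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[gi, ])^2)))
  })
  mean(sapply(seq_along(ks), function(i) {
    max(sapply(setdiff(seq_along(ks), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }))
  }))
}

# rank a distance row by sorting, self forced first, ties to lower index
oracle_rank_row <- function(d, self) {
  d[self] <- -Inf
  ord <- order(d, seq_along(d))
  r <- integer(length(d))
  r[ord] <- seq_along(d)
  r
}
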