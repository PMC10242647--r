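# Independent oracles, kept deliberately naive: direct enumeration / pairwise
# counting, no shared code with the implementation under test.

# AUC as the Mann-Whitney pairwise count with half credit for ties
oracle_auc_paircount <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exact two-sided rank-sum p by enumerating every assignment of the pooled
# values to the two groups; statistic = number of (x > y) pairs + half-ties
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    a <- pooled[ix]; b <- pooled[-ix]
    tot <- 0
    for (v in a) for (w in b) tot <- tot + (v > w) + 0.5 * (v == w)
    tot
  }
  obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n1 + n2, n1), 2L, u_of)
  min(1, 2 * min(mean(us <= obs + 1e-9), mean(us >= obs - 1e-9)))
}

# upper-tail hypergeometric p by enumerating every possible query draw
oracle_hyper_p <- function(overlap, set_size, universe_size, query_size) {
  marked <- seq_len(set_size)
  draws <- utils::combn(universe_size, query_size)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= overlap)
}

# Wilson interval as the roots of (phat - p)^2 = z^2 p (1 - p) / n
oracle_wilson <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- k / n
  a <- 1 + z^2 / n
  b <- -(2 * phat + z^2 / n)
  cc <- phat^2
  disc <- sqrt(b^2 - 4 * a * cc)
  c((-b - disc) / (2 * a), (-b + disc) / (2 * a))
}

# naive nearest-centroid score, written independently of the package
oracle_centroid_score <- function(X, train_idx, labels, test_j, features) {
  tr_pos <- train_idx[labels[train_idx] == "positive"]
  tr_neg <- train_idx[labels[train_idx] == "negative"]
  cp <- apply(X[features, tr_pos, drop = FALSE], 1L, mean)
  cn <- apply(X[features, tr_neg, drop = FALSE], 1L, mean)
  x <- X[features, test_j]
  sqrt(sum((x - cn)^2)) - sqrt(sum((x - cp)^2))
}
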