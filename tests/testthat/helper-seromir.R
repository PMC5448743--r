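# Shared fixture builders and independent oracles.

# Small Ct panel from a matrix spec; NA encodes undetermined wells.
make_panel <- function(ct) {
  ct_panel(ct)
}

# Exhaustive pairwise-comparison oracle for the AUC: enumerate every
# event x nonevent pair, counting ties as one half.
auc_pair_oracle <- function(scores, y) {
  e <- scores[y == 1]
  ne <- scores[y == 0]
  tot <- 0
  for (a in e) for (b in ne) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(e) * length(ne))
}

# Independent Newton-Raphson solver for logistic maximum likelihood.
newton_logistic <- function(X, y, tol = 1e-12, maxit = 50) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    step <- solve(crossprod(X, X * w), crossprod(X, y - p))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

# Probability/label vectors realising a given confusion matrix at 0.5.
probs_from_counts <- function(tp, fn, tn, fp) {
  list(probs = c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp)),
       labels = c(rep(1, tp + fn), rep(0, tn + fp)))
}

# NormFinder acceptance-style panel: planted gene-by-group biases summing
# exactly to zero over genes (the model's interaction constraint), with one
# designed clearly-stable gene ("g01": zero bias, low variance).
normfinder_truth_panel <- function(k = 20, n_g = 50) {
  n <- 2 * n_g
  g <- rep(c("a", "b"), each = n_g)
  m <- runif((k - 2) / 2, 0.5, 1.2)
  d <- c(0, 0, rbind(m, -m))
  sdw <- c(0.2, 1.5, runif(k - 2, 0.5, 1.5))
  samp <- rnorm(n, 0, 1)
  x <- matrix(rnorm(k * n), k, n) * sdw +
    outer(d / 2, ifelse(g == "b", 1, -1)) + rep(samp, each = k)
  rownames(x) <- sprintf("g%02d", seq_len(k))
  list(x = x, g = g, stable_gene = "g01",
       truth_score = abs(d) / 2 + sdw / sqrt(n_g))
}
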