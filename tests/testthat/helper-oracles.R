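# Independent brute-force reference implementations used to verify every
# encoder and metric. These loop over the defining sums directly and share
# no code with the package implementations.

rand_norm_profile <- function(L, seed, id = paste0("p", seed)) {
  set.seed(seed)
  m <- pmin(pmax(round(stats::rnorm(L * 20, 0, 3)), -10), 13)
  normalize_pssm(pssm_profile(id, matrix(m, nrow = L)))
}

oracle_aac <- function(P) {
  L <- nrow(P)
  v <- numeric(20)
  for (j in 1:20) {
    s <- 0
    for (i in 1:L) s <- s + P[i, j]
    v[j] <- s / L
  }
  v
}

oracle_tpc <- function(P) {
  L <- nrow(P)
  X <- matrix(0, 20, 20)
  for (i in 1:20) {
    num <- numeric(20)
    for (j in 1:20) {
      s <- 0
      for (k in 1:(L - 1)) s <- s + P[k, i] * P[k + 1, j]
      num[j] <- s
    }
    den <- sum(num)
    if (den > 0) X[i, ] <- num / den
  }
  as.vector(t(X))
}

# mean squared lag difference over rows a..b, divisor (b - a + 1 - lam)
.o_pse_seg <- function(P, a, b, lambdas) {
  out <- numeric(0)
  for (lam in lambdas) {
    v <- numeric(20)
    for (j in 1:20) {
      if (lam == 0) {
        s <- 0
        for (i in a:b) s <- s + P[i, j]
        v[j] <- s / (b - a + 1)
      } else {
        s <- 0
        for (i in a:(b - lam)) s <- s + (P[i, j] - P[i + lam, j])^2
        v[j] <- s / (b - a + 1 - lam)
      }
    }
    out <- c(out, v)
  }
  out
}

oracle_pse <- function(P, nseg) {
  L <- nrow(P)
  if (nseg == 2) {
    L1 <- floor(L / 2)
    c(.o_pse_seg(P, 1, L1, 0:4), .o_pse_seg(P, L1 + 1, L, 0:4))
  } else {
    L1 <- floor(L / 3)
    c(.o_pse_seg(P, 1, L1, 0:2),
      .o_pse_seg(P, L1 + 1, 2 * L1, 0:2),
      .o_pse_seg(P, 2 * L1 + 1, L, 0:2))
  }
}

.o_act_seg <- function(P, a, b, lags) {
  out <- numeric(0)
  for (lg in lags) {
    v <- numeric(20)
    for (j in 1:20) {
      m <- 0
      for (i in a:b) m <- m + P[i, j]
      m <- m / (b - a + 1)
      s <- 0
      for (i in a:(b - lg)) s <- s + (P[i, j] - m) * (P[i + lg, j] - m)
      v[j] <- s / (b - a + 1 - lg)
    }
    out <- c(out, v)
  }
  out
}

oracle_act <- function(P, nseg) {
  L <- nrow(P)
  if (nseg == 2) {
    L1 <- floor(L / 2)
    c(.o_act_seg(P, 1, L1, 1:4), .o_act_seg(P, L1 + 1, L, 1:4))
  } else {
    L1 <- floor(L / 3)
    c(.o_act_seg(P, 1, L1, 1:2),
      .o_act_seg(P, L1 + 1, 2 * L1, 1:2),
      .o_act_seg(P, 2 * L1 + 1, L, 1:2))
  }
}

oracle_cs <- function(P) {
  L <- nrow(P)
  cons <- integer(L)
  for (i in 1:L) cons[i] <- which(P[i, ] == max(P[i, ]))[1]
  csaac <- numeric(20)
  cscm <- numeric(20)
  for (j in 1:20) {
    csaac[j] <- sum(cons == j) / L
    cscm[j] <- sum(which(cons == j)) / (L * (L - 1))
  }
  c(csaac, cscm)
}

# direct evaluation of the printed metric formulas
oracle_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  list(acc = (tp + tn) / n,
       sens = tp / (tp + fn),
       spec = tn / (fp + tn),
       precision = tp / (tp + fp),
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn)) / sqrt((tn + fp) * (tn + fn)),
       bacc = (tp / (tp + fn) + tn / (fp + tn)) / 2)
}

# Mann-Whitney rank statistic: equals the trapezoidal ROC area
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# per-point kNN agreement check on z-scored features
oracle_enn_keep <- function(X, y, k, kind = "all") {
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sds[sds == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  n <- nrow(Z)
  maj <- if (sum(y == 1) > sum(y == 0)) 1 else 0
  keep <- rep(TRUE, n)
  for (i in which(y == maj)) {
    d <- sqrt(colSums((t(Z) - Z[i, ])^2))
    d[i] <- Inf
    nb <- order(d)[1:k]
    dis <- sum(y[nb] != y[i])
    keep[i] <- if (kind == "all") dis == 0 else dis <= k / 2
  }
  keep
}

# two Gaussian blobs as a feature table
blob_table <- function(n_pos, n_neg, d = 2, sep = 0, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_pos * d, mean = sep), n_pos, d),
             matrix(stats::rnorm(n_neg * d, mean = 0), n_neg, d))
  colnames(X) <- paste0("f", seq_len(d))
  feature_table(paste0("s", seq_len(n_pos + n_neg)), X,
                c(rep(1L, n_pos), rep(0L, n_neg)))
}
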