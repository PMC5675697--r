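# Independent brute-force oracles used to verify the package's statistics.
# Each is written from the defining formula, not by calling the code path
# it checks.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mann_whitney <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  combs <- utils::combn(m + n, m)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  u_all <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up from the definition: q_(i) = min_{k>=i} m p_(k)/k.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p_sorted[i:m] / seq(i, m)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Hypergeometric upper-tail by direct summation.
oracle_hyper_tail <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exact two-sided Spearman p by enumeration over all rank permutations of
# the rank-distance statistic S = sum d^2, doubling the tail on the
# observed side of its null mean (the standard exact two-sided convention).
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  perms <- perm_all(n)
  s_obs <- sum((rx - ry)^2)
  s_all <- apply(perms, 1, function(pp) sum((rx - ry[pp])^2))
  s_mean <- (n^3 - n) / 6
  tail <- if (s_obs > s_mean) mean(s_all >= s_obs - 1e-9)
          else mean(s_all <= s_obs + 1e-9)
  min(1, 2 * tail)
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[r, ] <- c(i, rest[sub[j, ]])
      r <- r + 1
    }
  }
  out
}

# Kaplan-Meier product-limit by the defining product, looped by hand.
oracle_km <- function(time, event) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  tu <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (tt in tu) {
    n_i <- sum(time >= tt)
    d_i <- sum(time == tt & event == 1)
    s <- s * (1 - d_i / n_i)
    out <- rbind(out, data.frame(time = tt, surv = s))
  }
  out
}

# Exact permutation null of the log-rank statistic over all distinct
# stratum labelings (for small n without ties in group sizes).
oracle_logrank_perm_p <- function(time, event, stratum) {
  obs <- splicegrade::logrank_test(time, event, stratum)$chi2
  n <- length(time)
  idx_a <- utils::combn(n, sum(stratum == unique(stratum)[1]))
  stats <- apply(idx_a, 2, function(ii) {
    lab <- rep("b", n); lab[ii] <- "a"
    suppressWarnings(splicegrade::logrank_test(time, event, lab)$chi2)
  })
  mean(stats >= obs - 1e-9)
}

# Simple linear regression slope test from closed-form algebra.
oracle_slope_test <- function(x, y) {
  n <- length(x)
  bx <- mean(x); by <- mean(y)
  sxx <- sum((x - bx)^2)
  beta <- sum((x - bx) * (y - by)) / sxx
  alpha <- by - beta * bx
  rss <- sum((y - alpha - beta * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- beta / se
  list(slope = beta, t = t, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Moderated t recomputed gene-by-gene from the posterior-variance formula.
oracle_moderated_t <- function(mat, design, contrast, d0, s2_prior) {
  sapply(seq_len(nrow(mat)), function(g) {
    y <- mat[g, ]
    groups <- unique(design)
    res <- y - ave(y, design)
    d <- length(y) - length(groups)
    s2 <- sum(res^2) / d
    s2_post <- if (is.infinite(d0)) s2_prior
               else (d0 * s2_prior + d * s2) / (d0 + d)
    fc <- mean(y[design == contrast[2]]) - mean(y[design == contrast[1]])
    fc / sqrt(s2_post * (1 / sum(design == contrast[1]) +
                           1 / sum(design == contrast[2])))
  })
}
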