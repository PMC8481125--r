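# Independent brute-force oracles, kept free of the code paths they check.

# Average ranks computed by explicit counting (no rank()).
oracle_avg_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    smaller <- sum(x < x[i])
    equal <- sum(x == x[i])
    smaller + (equal + 1) / 2
  }, numeric(1))
}

# Spearman's rho as the Pearson correlation of average ranks, from sum
# formulas only.
oracle_spearman <- function(x, y) {
  rx <- oracle_avg_ranks(x)
  ry <- oracle_avg_ranks(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Two-sided Fisher exact p by full enumeration over tables with the observed
# margins, summing hypergeometric probabilities of tables at most as
# probable as the observed one (with the conventional 1e-7 relative slack).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 margin
  n2 <- c + d         # row 2 margin
  k <- a + c          # column 1 margin
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mantel-Cox log-rank by explicit 2x2 tables at each pooled event time:
# observed and expected events for group A plus the hypergeometric variance.
oracle_logrank <- function(time, event, is_a) {
  ts <- sort(unique(time[event == 1]))
  oa <- ea <- va <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & is_a)
    d <- sum(event == 1 & time == t)
    d_a <- sum(event == 1 & time == t & is_a)
    oa <- oa + d_a
    ea <- ea + d * n_a / n
    if (n > 1) {
      va <- va + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
  }
  ob <- sum(event == 1 & !is_a)
  eb <- sum(event) - ea
  list(obs = c(oa, ob), exp = c(ea, eb), var = va,
       chisq = (oa - ea)^2 / va)
}

# Exhaustive best single split: all thresholds for numeric predictors, all
# 2^(L-1)-1 binary partitions (not the ordered-mean shortcut) for
# categoricals. Returns the maximal achievable goodness.
oracle_best_split_goodness <- function(y, x) {
  ss <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  parent <- ss(y)
  best <- -Inf
  for (j in seq_along(x)) {
    xj <- x[[j]]
    if (is.factor(xj) || is.character(xj)) {
      levs <- unique(as.character(xj))
      if (length(levs) < 2) next
      for (bits in 1:(2^(length(levs) - 1) - 1)) {
        left <- levs[as.logical(bitwAnd(bits, 2^(seq_along(levs) - 1)))]
        mask <- as.character(xj) %in% left
        if (!any(mask) || all(mask)) next
        best <- max(best, parent - ss(y[mask]) - ss(y[!mask]))
      }
    } else {
      u <- sort(unique(xj))
      if (length(u) < 2) next
      for (cut in (u[-1] + u[-length(u)]) / 2) {
        mask <- xj <= cut
        best <- max(best, parent - ss(y[mask]) - ss(y[!mask]))
      }
    }
  }
  best
}

# Dense grid search for the 0.5 crossing of a fitted logistic curve.
oracle_ic50_grid <- function(fit, doses) {
  grid <- 10^seq(log10(min(doses)), log10(max(doses)), length.out = 20000)
  f <- fit$fit$bottom + (fit$fit$top - fit$fit$bottom) /
    (1 + (grid / fit$fit$inflection)^fit$fit$hill)
  i <- which(f <= 0.5)[1]
  if (is.na(i)) return(NA_real_)
  grid[i]
}
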