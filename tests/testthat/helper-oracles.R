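# Independent oracles, coded as plain double loops / enumeration so they
# share no arithmetic with the package implementation.

# One-way ANOVA + ICC by explicit sums of squares; p-value by numerical
# integration of the F density (not pf()).
oracle_icc <- function(x, rho0 = 0.20) {
  n <- nrow(x)
  k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssb <- 0
  ssw <- 0
  for (i in seq_len(n)) {
    mi <- sum(x[i, ]) / k
    ssb <- ssb + k * (mi - grand)^2
    for (j in seq_len(k)) ssw <- ssw + (x[i, j] - mi)^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  f0 <- (msb / msw) * (1 - rho0) / (1 + (k - 1) * rho0)
  p <- stats::integrate(function(t) stats::df(t, n - 1, n * (k - 1)),
                        f0, Inf, rel.tol = 1e-9, stop.on.error = FALSE)$value
  list(msb = msb, msw = msw, icc = icc, f = f0, p = p)
}

# AUC by exhaustive case-control pair counting.
oracle_auc <- function(scores, labels) {
  cases <- scores[labels]
  controls <- scores[!labels]
  total <- 0
  for (a in cases) for (b in controls) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(cases) * length(controls))
}

# DeLong variance by explicitly materialised placement values.
oracle_delong_var <- function(scores, labels) {
  cases <- scores[labels]
  controls <- scores[!labels]
  m <- length(cases)
  n <- length(controls)
  v10 <- numeric(m)
  for (i in seq_len(m)) {
    s <- 0
    for (b in controls) s <- s + if (cases[i] > b) 1 else if (cases[i] == b) 0.5 else 0
    v10[i] <- s / n
  }
  v01 <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (a in cases) s <- s + if (a > controls[j]) 1 else if (a == controls[j]) 0.5 else 0
    v01[j] <- s / m
  }
  sum((v10 - mean(v10))^2) / (m - 1) / m + sum((v01 - mean(v01))^2) / (n - 1) / n
}

# Percentile by sort-and-interpolate at rank 1 + p (m - 1).
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- 1 + p * (length(s) - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Pearson chi-square statistic by the hand formula sum (O - E)^2 / E.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Sample size for the ICC test re-derived from the asymptotic normality of
# the log F ratio: solve power(n) = target for continuous n.
oracle_icc_n <- function(rho0, rho1, k, alpha, power, tails) {
  C <- function(r) (1 + (k - 1) * r) / (1 - r)
  pw <- function(n) {
    stats::pnorm(sqrt((n - 1) * (k - 1) / (2 * k)) * log(C(rho1) / C(rho0)) -
                   stats::qnorm(1 - alpha / tails))
  }
  stats::uniroot(function(n) pw(n) - power, c(1 + 1e-9, 1e6), tol = 1e-12)$root
}
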