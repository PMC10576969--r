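# Independent statistical oracles, kept deliberately separate from the
# package implementation: direct summation and closed forms only.

# One-way ANOVA by direct summation of sums of squares.
ss_anova_oracle <- function(values, labels) {
  keep <- !is.na(labels) & !is.na(values)
  v <- values[keep]; l <- labels[keep]
  groups <- unique(l)
  grand <- mean(v)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    x <- v[l == g]
    ssb <- ssb + length(x) * (mean(x) - grand)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  dfb <- length(groups) - 1
  dfw <- length(v) - length(groups)
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, df_between = dfb, df_within = dfw, ssb = ssb, ssw = ssw,
       p = pf(Fv, dfb, dfw, lower.tail = FALSE))
}

# OLS slope p-value through the correlation coefficient: t = r sqrt((n-2)/(1-r^2)).
r_to_t_oracle <- function(y, x) {
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  r <- cor(x, y)
  slope <- r * sd(y) / sd(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(slope = slope, p = 2 * pt(-abs(t), n - 2), n = n)
}

# Two-group pooled-variance t test, two-sided (Tukey with k = 2 must agree).
pooled_t_oracle <- function(a, b) {
  df <- length(a) + length(b) - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  2 * pt(-abs(t), df)
}

# Random small grouped instance for oracle-equivalence properties.
random_instance <- function() {
  k <- sample(2:4, 1)
  n <- sample(3:8, k, replace = TRUE)
  list(values = unlist(lapply(n, function(m)
         rnorm(m, mean = runif(1, -2, 2), sd = runif(1, 0.5, 2)))),
       labels = rep(paste0("g", seq_len(k)), n))
}
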