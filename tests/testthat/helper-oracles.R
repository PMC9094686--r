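# Independent brute-force oracles used to cross-check the implementation.

# glance count by literal scan-and-merge over a boolean focus sequence
oracle_glance_count <- function(t, on, max_gap, dt_last = NULL) {
  if (!any(on)) return(0L)
  if (is.null(dt_last)) dt_last <- median(diff(t))
  starts <- ends <- numeric(0)
  i <- 1
  n <- length(on)
  while (i <= n) {
    if (on[i]) {
      j <- i
      while (j < n && on[j + 1]) j <- j + 1
      starts <- c(starts, t[i])
      ends <- c(ends, if (j < n) t[j + 1] else t[j] + dt_last)
      i <- j + 1
    } else i <- i + 1
  }
  count <- 1L
  for (k in seq_along(starts)[-1])
    if (starts[k] - ends[k - 1] >= max_gap) count <- count + 1L
  count
}

# Mann-Whitney U by explicit double loop
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# acceleration sign changes by explicit finite-difference loop
oracle_accel_count <- function(x, y, z, tol = 1e-9) {
  count_axis <- function(v) {
    a <- numeric(length(v) - 2)
    for (i in 2:(length(v) - 1)) a[i - 1] <- v[i + 1] - 2 * v[i] + v[i - 1]
    s <- sign(a)
    s[abs(a) < tol] <- 0
    s <- s[s != 0]
    if (length(s) < 2) return(0L)
    sum(s[-1] != s[-length(s)])
  }
  count_axis(x) + count_axis(y) + count_axis(z)
}

# moving-median MAD outlier flags by literal sliding window
oracle_outlier_flags <- function(v, window, k) {
  n <- length(v)
  before <- window %/% 2
  after <- window - before - 1
  flag <- rep(FALSE, n)
  for (i in seq_len(n)) {
    w <- v[max(1, i - before):min(n, i + after)]
    w <- w[!is.na(w)]
    if (length(w) == 0 || is.na(v[i])) next
    m <- median(w)
    smad <- 1.4826 * median(abs(w - m))
    flag[i] <- abs(v[i] - m) > k * smad
  }
  flag
}

# balanced mixed-design ANOVA (one between, one within) by direct summation
oracle_mixed_2x2 <- function(d) {
  # d: subject, group, w, value; balanced groups, complete cells
  gm <- mean(d$value)
  subj_means <- tapply(d$value, d$subject, mean)
  grp_of <- tapply(as.character(d$group), d$subject, `[`, 1)
  grp_means <- tapply(d$value, d$group, mean)
  w_means <- tapply(d$value, d$w, mean)
  cell_gw <- tapply(d$value, list(d$group, d$w), mean)
  n_w <- length(unique(d$w))
  n_subj <- length(subj_means)
  ss_grp <- n_w * sum((grp_means[grp_of] - gm)^2) / table(grp_of)[1] *
    table(grp_of)[1]  # = n_w * sum over subjects of group dev^2
  ss_grp <- n_w * sum((grp_means[grp_of] - gm)^2)
  ss_subj_within <- n_w * sum((subj_means - grp_means[grp_of])^2)
  n_per_grp <- table(grp_of)
  ss_w <- n_subj * sum((w_means - gm)^2)
  ss_gw <- 0
  for (g in rownames(cell_gw)) for (w in colnames(cell_gw))
    ss_gw <- ss_gw + n_per_grp[g] *
      (cell_gw[g, w] - grp_means[g] - w_means[w] + gm)^2
  ss_tot <- sum((d$value - gm)^2)
  ss_err_w <- ss_tot - ss_grp - ss_subj_within - ss_w - ss_gw
  list(ss_group = unname(ss_grp), ss_subj = unname(ss_subj_within),
       ss_w = unname(ss_w), ss_gw = unname(ss_gw),
       ss_err_w = unname(ss_err_w), ss_tot = ss_tot)
}
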