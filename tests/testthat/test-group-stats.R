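test_that("one-way ANOVA: degenerate, algebraic, and partition checks", {
  g <- rep(c("a", "b", "c"), each = 4)
  ident <- oneway_anova(rep(c(1, 2, 3, 4), 3), g)
  expect_equal(ident$table$statistic[1], 0)
  expect_equal(ident$eta_sq, 0)

  set.seed(10)
  a <- rnorm(8); b <- rnorm(9, 1)
  res <- oneway_anova(c(a, b), rep(c("a", "b"), c(8, 9)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$table$statistic[1], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res$table$p[1], tt$p.value, tolerance = 1e-10)

  v2 <- c(3, 4, 5, 6, 7, 9, 2, 2, 4)
  res2 <- oneway_anova(v2, rep(c("a", "b", "c"), each = 3))
  # direct-summation oracle
  gm <- mean(v2)
  means <- tapply(v2, rep(c("a", "b", "c"), each = 3), mean)
  ss_b <- 3 * sum((means - gm)^2)
  ss_t <- sum((v2 - gm)^2)
  expect_equal(res2$table$ss[1], ss_b, tolerance = 1e-10)
  expect_equal(sum(res2$table$ss), ss_t, tolerance = 1e-10)
  expect_equal(res2$eta_sq, ss_b / ss_t, tolerance = 1e-10)

  expect_error(oneway_anova(1:5, c("a", "a", "a", "a", "b")), "at least 2")
})

test_that("mixed rmANOVA matches a direct-summation oracle on a balanced
           two-group by two-level design", {
  set.seed(11)
  d <- expand.grid(subject = sprintf("s%02d", 1:8), w = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%02d", 1:4), "g1", "g2")
  d$value <- rnorm(nrow(d)) + 2 * (d$group == "g2") +
    0.8 * (d$w == "w2") + 1.2 * (d$group == "g2" & d$w == "w2")
  res <- mixed_rm_anova(d, dv = "value", subject = "subject",
                        within = "w", between = "group")
  o <- oracle_mixed_2x2(d)
  tab <- res$table
  expect_equal(tab$ss[tab$effect == "group"], o$ss_group, tolerance = 1e-8)
  expect_equal(tab$error_ss[tab$effect == "group"], o$ss_subj,
               tolerance = 1e-8)
  expect_equal(tab$ss[tab$effect == "w"], o$ss_w, tolerance = 1e-8)
  expect_equal(tab$ss[tab$effect == "group:w"], o$ss_gw, tolerance = 1e-8)
  expect_equal(tab$error_ss[tab$effect == "w"], o$ss_err_w, tolerance = 1e-8)
  # SS partition and the eta-squared definitions
  expect_equal(sum(tab$ss) + res$total_error_ss, o$ss_tot, tolerance = 1e-8)
  expect_equal(tab$pes, tab$ss / (tab$ss + tab$error_ss), tolerance = 1e-12)
  expect_equal(tab$ges, tab$ss / (tab$ss + o$ss_subj + o$ss_err_w),
               tolerance = 1e-10)
  # F ratios against the oracle decomposition
  expect_equal(tab$statistic[tab$effect == "group"],
               (o$ss_group / 1) / (o$ss_subj / 6), tolerance = 1e-8)
  expect_equal(tab$statistic[tab$effect == "w"],
               (o$ss_w / 1) / (o$ss_err_w / 6), tolerance = 1e-8)
})

test_that("rmANOVA effect-size inequalities hold on random designs", {
  set.seed(12)
  for (i in 1:20) {
    n_g <- sample(2:3, 1)
    n_s <- sample(c(4, 6), 1)           # per group (balanced)
    n_w <- sample(2:3, 1)
    subj <- sprintf("s%02d", seq_len(n_g * n_s))
    d <- expand.grid(subject = subj, w = paste0("w", seq_len(n_w)),
                     stringsAsFactors = FALSE)
    d$group <- paste0("g", (match(d$subject, subj) - 1) %/% n_s + 1)
    d$value <- rnorm(nrow(d))
    res <- mixed_rm_anova(d, "value", "subject", within = "w",
                          between = "group")
    tab <- res$table
    expect_true(all(tab$ss >= 0))
    expect_true(all(tab$ges <= tab$pes + 1e-12))
    expect_true(all(tab$pes >= 0 & tab$pes <= 1))
    # balanced design: effects plus error strata partition the total SS
    tot <- sum((d$value - mean(d$value))^2)
    expect_equal(sum(tab$ss) + res$total_error_ss, tot, tolerance = 1e-8)
  }
})

test_that("zero within-subject variation gives zero within F", {
  d <- expand.grid(subject = sprintf("s%d", 1:6), w = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:3), "g1", "g2")
  base <- c(1, 2, 3, 4, 5, 6)
  d$value <- base[match(d$subject, sprintf("s%d", 1:6))]
  res <- mixed_rm_anova(d, "value", "subject", within = "w",
                        between = "group")
  expect_equal(res$table$ss[res$table$effect == "w"], 0, tolerance = 1e-12)
})

test_that("purely between designs have one error term so pes equals ges", {
  set.seed(13)
  d <- data.frame(subject = sprintf("s%d", 1:15),
                  group = rep(c("a", "b", "c"), each = 5),
                  value = rnorm(15))
  res <- mixed_rm_anova(d, "value", "subject", within = NULL,
                        between = "group")
  expect_equal(res$table$pes, res$table$ges, tolerance = 1e-12)
  ow <- oneway_anova(d$value, d$group)
  expect_equal(res$table$statistic, ow$table$statistic[1], tolerance = 1e-8)
  expect_equal(res$table$pes, ow$eta_sq, tolerance = 1e-10)
})

test_that("missing within-subject cells are reported with subject and cell", {
  d <- expand.grid(subject = c("s1", "s2", "s3", "s4"), w = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$group <- rep(c("g1", "g2"), each = 2)[match(d$subject,
                                                c("s1", "s2", "s3", "s4"))]
  d$value <- rnorm(8)
  d <- d[-3, ]
  expect_error(mixed_rm_anova(d, "value", "subject", "w", "group"),
               "missing within-subject cell: subject s3")
})

test_that("t reports carry Glass delta and Hedges g1 as defined", {
  a <- c(1, 2, 3, 4)
  expect_equal(t_test_report(a, a)$statistic, 0)
  expect_equal(t_test_report(a, a)$effect_size, 0)

  set.seed(14)
  b <- rnorm(12, 10, 2)
  res <- t_test_report(b + sd(b), b)
  expect_equal(res$effect_size, 1, tolerance = 1e-10)
  tt <- t.test(b + sd(b), b, var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)

  zero_sd <- t_test_report(c(1, 2, 3), c(5, 5, 5))
  expect_true(zero_sd$effect_size_undefined)

  one <- t_test_report(b, mu = 9)
  J <- 1 - 3 / (4 * 11 - 1)
  expect_equal(one$effect_size, J * (mean(b) - 9) / sd(b), tolerance = 1e-12)
  expect_equal(one$effect_size_name, "hedges_g1")
})

test_that("Mann-Whitney U: worked example, symmetry, U3 orientation", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 9)       # max(U, n1 n2 - U) convention
  expect_equal(res$u_a, 0)
  expect_equal(res$u3, 0)

  x <- c(1, 2, 3, 4)
  expect_equal(mann_whitney_u(x, x)$u_a, 8)     # n1 n2 / 2 under identity
  expect_equal(mann_whitney_u(x, x)$u3, 0.5)    # ties counted half

  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney U equals the double-loop pair count", {
  set.seed(15)
  for (i in 1:100) {
    a <- sample(0:20, sample(3:12, 1), replace = TRUE)
    b <- sample(0:20, sample(3:12, 1), replace = TRUE)
    res <- mann_whitney_u(a, b)
    u <- oracle_u(a, b)
    expect_equal(res$u_a, u)
    expect_equal(res$statistic, max(u, length(a) * length(b) - u))
  }
})

test_that("empirical type-I error of the group tests is near nominal", {
  set.seed(16)
  n_sim <- 2000
  rej <- c(anova = 0, kw = 0, mwu = 0, t = 0)
  for (i in seq_len(n_sim)) {
    v <- rnorm(24)
    g <- rep(c("a", "b", "c"), each = 8)
    if (oneway_anova(v, g)$table$p[1] < 0.05) rej["anova"] <- rej["anova"] + 1
    if (kruskal_wallis(v, g)$p < 0.05) rej["kw"] <- rej["kw"] + 1
    if (mann_whitney_u(v[1:8], v[9:16])$p < 0.05) rej["mwu"] <- rej["mwu"] + 1
    if (t_test_report(v[1:8], v[9:16])$p < 0.05) rej["t"] <- rej["t"] + 1
  }
  rates <- rej / n_sim
  expect_true(all(rates >= 0.03 & rates <= 0.07))
})

test_that("correlations and the partial Spearman recursion", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(cor_report(x, x, "spearman")$statistic, 1)
  expect_equal(cor_report(x, 2 * x + 1, "pearson")$statistic, 1,
               tolerance = 1e-12)
  expect_true(cor_report(x, rep(1, 8))$undefined)

  set.seed(17)
  z <- rnorm(8)
  expect_equal(partial_spearman(x, x, z)$statistic, 1, tolerance = 1e-10)

  # residual-regression oracle on a 5-row table
  x5 <- c(2, 7, 4, 9, 1); y5 <- c(5, 3, 8, 2, 6); z5 <- c(1, 4, 2, 5, 3)
  rx <- rank(x5); ry <- rank(y5); rz <- rank(z5)
  ex <- residuals(lm(rx ~ rz)); ey <- residuals(lm(ry ~ rz))
  expect_equal(partial_spearman(x5, y5, z5)$statistic, cor(ex, ey),
               tolerance = 1e-12)

  # a control orthogonal to both rank vectors leaves Spearman unchanged
  x8 <- 1:8; y8 <- c(2, 1, 4, 3, 6, 5, 8, 7)
  z8 <- c(1, 1, -1, -1, -1, -1, 1, 1)  # rank pattern orthogonal to both
  expect_equal(partial_spearman(x8, y8, z8)$statistic,
               cor_report(x8, y8, "spearman")$statistic, tolerance = 1e-10)
})

test_that("Bonferroni threshold: worked value, base case, monotonicity", {
  expect_equal(round(bonferroni_threshold(0.05, 3 * 54), 5), 0.00031)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  m <- c(1, 2, 10, 54, 162, 1000)
  th <- vapply(m, function(mm) bonferroni_threshold(0.05, mm), numeric(1))
  expect_true(all(diff(th) < 0))
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})
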