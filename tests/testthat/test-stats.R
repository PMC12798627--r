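test_that("signed-rank RBC hits its closed-form anchors", {
  r1 <- wilcoxon_rbc(rep(0, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(r1$effect_size, 1)
  expect_warning(r2 <- wilcoxon_rbc(rep(0, 4), c(1, -1, 2, -2)), "fewer than 5")
  expect_equal(r2$effect_size, 0)
  r3 <- wilcoxon_rbc(c(1, 1), c(1, 1))
  expect_true(is.na(r3$p_raw))
  expect_match(r3$note, "zero")
})

test_that("small-n signed-rank p equals exact enumeration and wilcox.test", {
  d <- c(1, 2, 3, 4, 5, -6)
  res <- wilcoxon_rbc(rep(0, 6), d)
  # brute force over all 2^6 sign assignments, written independently
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(-1, 1)), 6))
  w_all <- apply(grid, 1, function(sg) sum(r[sg > 0]))
  p_brute <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(res$p_raw, p_brute, tolerance = 1e-12)
  expect_equal(res$p_raw, wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(unname(res$statistic), unname(wilcox.test(d, exact = TRUE)$statistic))
  # a second fixture with ties exercises the mid-rank conditional enumeration
  d2 <- c(1, 1, -2, 3, 3, 4, -4)
  res2 <- wilcoxon_rbc(rep(0, 7), d2)
  r2 <- rank(abs(d2))
  w2 <- sum(r2[d2 > 0])
  grid2 <- expand.grid(rep(list(c(-1, 1)), 7))
  w_all2 <- apply(grid2, 1, function(sg) sum(r2[sg > 0]))
  p2 <- min(1, 2 * min(mean(w_all2 <= w2), mean(w_all2 >= w2)))
  expect_equal(res2$p_raw, p2, tolerance = 1e-12)
})

test_that("large-n signed-rank matches the reference normal approximation", {
  set.seed(31)
  a <- rnorm(40); b <- rnorm(40, 0.3)
  res <- wilcoxon_rbc(a, b)
  ref <- wilcox.test(b - a, exact = FALSE, correct = TRUE)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney U hits its anchors and the enumeration oracle", {
  expect_equal(mann_whitney_rbc(c(5, 6, 7), c(1, 2, 3))$effect_size, 1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  expect_equal(mann_whitney_rbc(x, y)$effect_size, 0)
  # exact p over all C(8,4) labelings vs wilcox.test
  x4 <- c(1.2, 3.4, 0.5, 2.2); y4 <- c(2.1, 4.4, 3.3, 5.0)
  res <- mann_whitney_rbc(x4, y4)
  ref <- wilcox.test(x4, y4, exact = TRUE)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(res$statistic), unname(ref$statistic))
  # independent brute force with ties present
  xt <- c(1, 2, 2, 5); yt <- c(2, 3, 6)
  rest <- mann_whitney_rbc(xt, yt)
  pooled <- c(xt, yt)
  rk <- rank(pooled)
  u_obs <- sum(rk[1:4]) - 4 * 5 / 2
  combs <- combn(7, 4)
  u_all <- apply(combs, 2, function(ix) sum(rk[ix]) - 4 * 5 / 2)
  p_brute <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(rest$p_raw, p_brute, tolerance = 1e-12)
  # large-sample path matches the reference implementation
  set.seed(8)
  xl <- rnorm(20); yl <- rnorm(25, 0.4)
  expect_equal(mann_whitney_rbc(xl, yl)$p_raw,
               wilcox.test(xl, yl, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(mann_whitney_rbc(numeric(0), yl), "non-empty")
})

test_that("BH and Holm corrections match hand computations and family logic", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(holm_adjust(c(0.001, 0.02, 0.04)), c(0.003, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  # families are corrected independently
  p <- c(0.01, 0.02, 0.03, 0.04)
  fam <- c("a", "b", "a", "b")
  got <- fdr_bh(p, fam)
  expect_equal(got[c(1, 3)], fdr_bh(p[c(1, 3)]))
  expect_equal(got[c(2, 4)], fdr_bh(p[c(2, 4)]))
  # permutation equivariance + step-up monotonicity
  set.seed(2)
  p2 <- runif(15)
  perm <- sample(15)
  expect_equal(fdr_bh(p2)[perm], fdr_bh(p2[perm]))
  adj <- fdr_bh(p2)
  expect_true(all(diff(adj[order(p2)]) >= -1e-12))
})

test_that("rmANOVA matches an independent sums-of-squares oracle on a toy table", {
  set.seed(77)
  Y <- matrix(rnorm(12), 4, 3) + outer(rep(0, 4), c(0, 1, 2), "+")
  fit <- rm_anova_gg(long_table(Y), "time_only")
  n <- 4; k <- 3
  grand <- mean(Y)
  ss_time <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_err <- sum((Y - outer(rowMeans(Y), rep(1, k)) -
                   outer(rep(1, n), colMeans(Y)) + grand)^2)
  F_or <- (ss_time / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  tab <- fit$table[fit$table$effect == "time", ]
  expect_equal(tab$ss, ss_time, tolerance = 1e-10)
  expect_equal(tab$F, F_or, tolerance = 1e-10)
  expect_equal(tab$df1, k - 1)
  expect_equal(tab$df2, (n - 1) * (k - 1))
  expect_equal(tab$eta2_g, ss_time / (ss_time + ss_subj + ss_err),
               tolerance = 1e-10)
  # epsilon from the double-centered covariance eigenvalues
  S <- cov(Y)
  C <- qr.Q(qr(contr.helmert(k)))
  Tm <- t(C) %*% S %*% C
  ev <- eigen(Tm, only.values = TRUE)$values
  expect_equal(fit$epsilon, sum(ev)^2 / ((k - 1) * sum(ev^2)), tolerance = 1e-10)
})

test_that("rmANOVA agrees with base-R references for mixed and sphericity paths", {
  set.seed(42)
  n <- 12; k <- 4
  Y <- matrix(rnorm(n * k), n, k) + outer(rnorm(n), rep(1, k))
  tech <- rep(c("MindGym", "VR"), each = n / 2)
  df <- long_table(Y, tech = tech)
  fit <- rm_anova_gg(df, "time_by_tech")
  av <- summary(stats::aov(value ~ tech * factor(timepoint) +
                             Error(participant / factor(timepoint)),
                           data = df))
  between <- av[["Error: participant"]][[1]]
  within <- av[["Error: participant:factor(timepoint)"]][[1]]
  tt <- fit$table
  expect_equal(tt$F[tt$effect == "tech"], between["tech", "F value"],
               tolerance = 1e-8)
  expect_equal(tt$F[tt$effect == "time"],
               within["factor(timepoint)", "F value"], tolerance = 1e-8)
  expect_equal(tt$F[tt$effect == "time:tech"],
               within["tech:factor(timepoint)", "F value"], tolerance = 1e-8)
  # Mauchly W against stats::mauchly.test, epsilon against anova.mlm
  ml <- stats::lm(Y ~ 1)
  expect_equal(fit_w <- rm_anova_gg(long_table(Y), "time_only")$mauchly_w,
               unname(stats::mauchly.test(ml, X = ~1)$statistic),
               tolerance = 1e-8)
  av2 <- stats::anova(ml, idata = data.frame(time = factor(1:k)), X = ~1,
                      test = "Spherical")
  gg_line <- grep("Greenhouse-Geisser", utils::capture.output(print(av2)),
                  value = TRUE)
  gg_ref <- as.numeric(sub(".*epsilon:\\s*", "", gg_line))
  expect_equal(rm_anova_gg(long_table(Y), "time_only")$epsilon, gg_ref,
               tolerance = 1e-3)
})

test_that("two timepoints force epsilon 1 with corrected = uncorrected", {
  set.seed(5)
  Y <- matrix(rnorm(20), 10, 2)
  fit <- rm_anova_gg(long_table(Y), "time_only")
  expect_equal(fit$epsilon, 1)
  expect_false(fit$correction_applied)
  expect_equal(fit$table$p_corrected, fit$table$p_uncorrected)
})

test_that("a pure between-group shift leaves the time effect flat", {
  set.seed(6)
  n <- 16; k <- 3
  Y <- matrix(rnorm(n * k, sd = 0.2), n, k)
  shift <- rep(c(0, 5), each = n / 2)
  Y <- Y + outer(shift, rep(1, k))
  df <- long_table(Y, tech = rep(c("MindGym", "VR"), each = n / 2))
  fit <- rm_anova_gg(df, "time_by_tech")
  tt <- fit$table
  expect_gt(tt$F[tt$effect == "tech"], 100)
  expect_lt(tt$F[tt$effect == "time"], 5)
  # between-effect consistent with a two-sample t on subject means
  t_ref <- t.test(rowMeans(Y) ~ rep(c("a", "b"), each = n / 2), var.equal = TRUE)
  expect_equal(tt$F[tt$effect == "tech"], unname(t_ref$statistic)^2,
               tolerance = 1e-8)
})

test_that("listwise deletion drops incomplete participants with a count", {
  set.seed(7)
  Y <- matrix(rnorm(15), 5, 3)
  df <- long_table(Y)
  df$value[df$participant == "p002" & df$timepoint == 2] <- NA
  fit <- rm_anova_gg(df, "time_only")
  expect_equal(fit$n_subjects, 4)
  expect_equal(fit$n_dropped, 1)
})

test_that("Holm post-hocs match hand values and paired d closed forms", {
  # constant shift +1 with sd 1 -> d = 1
  set.seed(9)
  base <- rnorm(30)
  d1 <- rnorm(30, 1, 1)
  df <- tibble::tibble(
    participant = rep(sprintf("p%02d", 1:30), 2),
    timepoint = rep(c(1, 2), each = 30),
    value = c(base, base + d1),
    stim = "Breathwork"
  )
  res <- holm_posthoc_paired(df, list(c(1, 2)))
  expect_equal(res$cohens_d, mean(d1) / sd(d1), tolerance = 1e-10)
  expect_equal(res$p_adjusted, res$p_raw)  # single contrast: Holm = raw
  # zero-variance differences are flagged
  df0 <- df
  df0$value[df0$timepoint == 2] <- df0$value[df0$timepoint == 1] + 1
  res0 <- holm_posthoc_paired(df0, list(c(1, 2)))
  expect_true(is.na(res0$statistic))
  expect_match(res0$note, "zero-variance")
})

test_that("tidy and glance return the broom-shaped summaries", {
  set.seed(10)
  fit <- rm_anova_gg(long_table(matrix(rnorm(30), 10, 3)), "time_only")
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("effect", "F", "p_corrected", "eta2_g") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("epsilon", "mauchly_p", "correction_applied") %in% names(gl)))
})
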