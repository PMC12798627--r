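#' Mixed repeated-measures ANOVA with sphericity handling
#'
#' Univariate mixed ANOVA for one within-subject factor (timepoint) and up
#' to two between-subject factors (tech, stim). Complete cases only
#' (participants missing any timepoint are dropped listwise, with a note).
#' Sums of squares are computed by the classical stratification: subject
#' means carry the between-subject effects (error: subjects within groups),
#' within-subject deviations carry the time effects (error: time-by-subject
#' within groups); each stratum uses marginal (Type III, sum-to-zero coded)
#' sums of squares so unequal group sizes are handled.
#'
#' Sphericity of the within-factor covariance is tested with Mauchly's W
#' (chi-square approximation on the pooled within-group covariance); when
#' Mauchly's p < .05 and there are more than two timepoints, the
#' Greenhouse-Geisser epsilon — from the eigenvalue spectrum of the
#' double-centered covariance — multiplies both degrees of freedom of every
#' within-stratum test. Both the uncorrected and the corrected p-value are
#' reported. Effect sizes are generalized eta-squared: SS_effect divided by
#' SS_effect plus every error-stratum SS (all factors here are manipulated).
#'
#' @param data Long tibble with columns `participant`, `tech`, `stim`,
#'   `timepoint`, `value` (see [features_long()]).
#' @param model Which design to fit: time only, time crossed with one
#'   between factor, or the full three-way mixed design.
#' @param sphericity_alpha Mauchly p-value below which the correction is
#'   applied.
#' @return Object of class `rm_anova`: list with `table` (one row per
#'   effect: `effect`, `df1`, `df2`, `F`, `p_uncorrected`, `df1_adj`,
#'   `df2_adj`, `p_corrected`, `eta2_g`, `stratum`), `epsilon`,
#'   `mauchly_w`, `mauchly_p`, `correction_applied`, `n_subjects`,
#'   `n_timepoints`, `n_dropped`, `model`.
#' @seealso [generics::tidy()] and [generics::glance()] methods are
#'   provided.
#' @export
rm_anova_gg <- function(data,
                        model = c("time_only", "time_by_tech", "time_by_stim",
                                  "time_by_tech_by_stim"),
                        sphericity_alpha = 0.05) {
  model <- match.arg(model)
  stopifnot(all(c("participant", "timepoint", "value") %in% names(data)))
  between <- switch(model,
                    time_only = character(0),
                    time_by_tech = "tech",
                    time_by_stim = "stim",
                    time_by_tech_by_stim = c("tech", "stim"))
  if (length(between) && !all(between %in% names(data))) {
    stop("model '", model, "' needs columns: ", paste(between, collapse = ", "))
  }

  wide <- tidyr::pivot_wider(
    data[, c("participant", between, "timepoint", "value")],
    names_from = "timepoint", values_from = "value"
  )
  k <- length(unique(data$timepoint))
  tp_cols <- setdiff(names(wide), c("participant", between))
  if (length(tp_cols) != k) stop("each participant must have one value per timepoint")
  complete <- stats::complete.cases(wide)
  n_dropped <- sum(!complete)
  wide <- wide[complete, ]
  n <- nrow(wide)
  if (n < 2L) stop("fewer than 2 complete subjects")
  if (k < 2L) stop("need at least 2 timepoints")
  Y <- as.matrix(wide[, tp_cols])

  # group structure for the covariance pooling
  grp <- if (length(between)) interaction(wide[, between], drop = TRUE) else
    factor(rep("all", n))
  if (any(table(grp) == 0)) stop("empty design cell")

  # ---- between stratum: subject means ----
  m <- rowMeans(Y)
  bdat <- as.data.frame(wide[, between, drop = FALSE])
  for (b in between) bdat[[b]] <- factor(bdat[[b]])
  if (length(between)) {
    form <- stats::as.formula(paste("~", paste(between, collapse = "*")))
    contr <- stats::setNames(rep(list("contr.sum"), length(between)), between)
    Xb <- stats::model.matrix(form, bdat, contrasts.arg = contr)
  } else {
    Xb <- matrix(1, n, 1)
    attr(Xb, "assign") <- 0L
  }
  assign_b <- attr(Xb, "assign")
  terms_b <- if (length(between)) attr(stats::terms(
    stats::as.formula(paste("~", paste(between, collapse = "*")))), "term.labels") else character(0)
  sse <- function(X, y) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  sse_b_full <- sse(Xb, m)
  ss_subj <- k * sse_b_full
  df_subj <- n - ncol(Xb)
  rows <- list()
  for (ti in seq_along(terms_b)) {
    keep <- assign_b != ti
    ss <- k * (sse(Xb[, keep, drop = FALSE], m) - sse_b_full)
    df1 <- sum(assign_b == ti)
    rows[[terms_b[ti]]] <- list(effect = terms_b[ti], ss = max(ss, 0), df1 = df1,
                                stratum = "between")
  }

  # ---- within stratum: subject-centered deviations ----
  W <- Y - m
  w <- as.vector(t(W))  # subject-major: rows are (subject, time) pairs
  time_f <- factor(rep(seq_len(k), times = n))
  wdat <- data.frame(time = time_f)
  for (b in between) wdat[[b]] <- factor(rep(bdat[[b]], each = k))
  rhs <- if (length(between)) paste("time *", paste(between, collapse = " * ")) else "time"
  contr_w <- stats::setNames(rep(list("contr.sum"), length(between) + 1L),
                             c("time", between))
  Xall <- stats::model.matrix(stats::as.formula(paste("~", rhs)), wdat,
                              contrasts.arg = contr_w)
  assign_all <- attr(Xall, "assign")
  terms_all <- attr(stats::terms(stats::as.formula(paste("~", rhs))), "term.labels")
  time_terms <- which(vapply(terms_all, function(t)
    "time" %in% strsplit(t, ":", fixed = TRUE)[[1]], logical(1)))
  keep_cols <- assign_all %in% time_terms
  Xw <- Xall[, keep_cols, drop = FALSE]
  assign_w <- assign_all[keep_cols]
  sse_w_full <- sse(Xw, w)
  ss_werr <- sse_w_full
  df_werr <- n * (k - 1) - ncol(Xw)
  for (ti in time_terms) {
    keep <- assign_w != ti
    ss <- if (any(keep)) sse(Xw[, keep, drop = FALSE], w) - sse_w_full else
      sum(w^2) - sse_w_full
    df1 <- sum(assign_w == ti)
    rows[[terms_all[ti]]] <- list(effect = terms_all[ti], ss = max(ss, 0),
                                  df1 = df1, stratum = "within")
  }

  # ---- sphericity: pooled within-group covariance ----
  df_cov <- n - nlevels(grp)
  mauchly_w <- NA_real_; mauchly_p <- NA_real_; eps <- 1
  if (k > 2L) {
    S <- matrix(0, k, k)
    for (g in levels(grp)) {
      Yg <- Y[grp == g, , drop = FALSE]
      if (nrow(Yg) > 1L) S <- S + stats::cov(Yg) * (nrow(Yg) - 1L)
    }
    S <- S / df_cov
    C <- qr.Q(qr(stats::contr.helmert(k)))  # orthonormal contrasts, k x (k-1)
    Tm <- t(C) %*% S %*% C
    ev_t <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
    eps <- sum(ev_t)^2 / ((k - 1) * sum(ev_t^2))
    if (df_cov >= k && all(ev_t > 1e-12)) {
      wstat <- det(Tm) / (sum(diag(Tm)) / (k - 1))^(k - 1)
      dd <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * df_cov)
      chi2 <- -df_cov * dd * log(wstat)
      df_m <- k * (k - 1) / 2 - 1
      mauchly_w <- wstat
      mauchly_p <- stats::pchisq(chi2, df_m, lower.tail = FALSE)
    }
  }
  correct <- k > 2L && is.finite(mauchly_p) && mauchly_p < sphericity_alpha

  # ---- assemble table ----
  tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  tab$df2 <- ifelse(tab$stratum == "between", df_subj, df_werr)
  err_ms <- ifelse(tab$stratum == "between", ss_subj / df_subj, ss_werr / df_werr)
  tab$F <- (tab$ss / tab$df1) / err_ms
  tab$p_uncorrected <- stats::pf(tab$F, tab$df1, tab$df2, lower.tail = FALSE)
  tab$df1_adj <- ifelse(tab$stratum == "within" & correct, tab$df1 * eps, tab$df1)
  tab$df2_adj <- ifelse(tab$stratum == "within" & correct, tab$df2 * eps, tab$df2)
  tab$p_corrected <- stats::pf(tab$F, tab$df1_adj, tab$df2_adj, lower.tail = FALSE)
  tab$eta2_g <- tab$ss / (tab$ss + ss_subj + ss_werr)
  tab <- tab[, c("effect", "stratum", "ss", "df1", "df2", "F",
                 "p_uncorrected", "df1_adj", "df2_adj", "p_corrected", "eta2_g")]

  structure(list(table = tab, epsilon = eps, mauchly_w = mauchly_w,
                 mauchly_p = mauchly_p, correction_applied = correct,
                 ss_subjects = ss_subj, ss_within_error = ss_werr,
                 df_subjects = df_subj, df_within_error = df_werr,
                 n_subjects = n, n_timepoints = k, n_dropped = n_dropped,
                 model = model),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA (%s): %d subjects x %d timepoints",
              x$model, x$n_subjects, x$n_timepoints))
  if (x$n_dropped) cat(sprintf(" (%d dropped listwise)", x$n_dropped))
  cat("\n")
  if (is.finite(x$mauchly_p)) {
    cat(sprintf("Mauchly W = %.4f, p = %.4g; Greenhouse-Geisser epsilon = %.4f%s\n",
                x$mauchly_w, x$mauchly_p, x$epsilon,
                if (x$correction_applied) " (applied)" else " (not applied)"))
  }
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an rm_anova fit
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return The effect table as a tibble (one row per effect).
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' One-row summary of an rm_anova fit
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return One-row tibble with the design size, sphericity diagnostics and
#'   whether the Greenhouse-Geisser correction was applied.
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(model = x$model, n_subjects = x$n_subjects,
                 n_timepoints = x$n_timepoints, n_dropped = x$n_dropped,
                 epsilon = x$epsilon, mauchly_w = x$mauchly_w,
                 mauchly_p = x$mauchly_p,
                 correction_applied = x$correction_applied)
}

#' Holm-corrected paired post-hoc t-tests between timepoints
#'
#' For each requested timepoint pair (within each level of the grouping
#' column, when given) a paired t-test is computed on the participants
#' complete for both timepoints; the whole set of contrasts forms one Holm
#' family. The effect size is Cohen's d for paired designs,
#' mean(difference) / sd(difference).
#'
#' @param data Long tibble as in [rm_anova_gg()].
#' @param pairs List of 2-element timepoint vectors, e.g.
#'   `list(c(1, 5), c(1, 2))`.
#' @param group Optional column name (e.g. `"stim"`): contrasts are computed
#'   within each of its levels.
#' @return Tibble with one row per contrast: `group`, `t_a`, `t_b`,
#'   `statistic` (t), `df`, `p_raw`, `p_adjusted` (Holm), `cohens_d`, `n`,
#'   `note`.
#' @export
holm_posthoc_paired <- function(data, pairs, group = NULL) {
  lvls <- if (is.null(group)) "all" else unique(data[[group]])
  rows <- list()
  for (g in lvls) {
    sub <- if (is.null(group)) data else data[data[[group]] == g, ]
    for (pr in pairs) {
      a <- sub[sub$timepoint == pr[1], c("participant", "value")]
      b <- sub[sub$timepoint == pr[2], c("participant", "value")]
      mrg <- merge(a, b, by = "participant", suffixes = c("_a", "_b"))
      d <- mrg$value_b - mrg$value_a
      d <- d[!is.na(d)]
      nd <- length(d)
      if (nd < 2L || stats::sd(d) < 1e-12) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = as.character(g), t_a = pr[1], t_b = pr[2],
          statistic = NA_real_, df = NA_real_, p_raw = NA_real_,
          cohens_d = NA_real_, n = nd,
          note = if (nd < 2L) "too few pairs" else "zero-variance differences: t undefined")
        next
      }
      tt <- stats::t.test(d)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = as.character(g), t_a = pr[1], t_b = pr[2],
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_raw = tt$p.value, cohens_d = mean(d) / stats::sd(d), n = nd,
        note = "")
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out[, c("group", "t_a", "t_b", "statistic", "df", "p_raw", "p_adjusted",
          "cohens_d", "n", "note")]
}
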