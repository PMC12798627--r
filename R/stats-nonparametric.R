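#' Wilcoxon signed-rank test with matched rank-biserial correlation
#'
#' Tests the paired change `post - pre`. Zero differences are dropped,
#' absolute differences are mid-ranked, and W is the sum of positive-signed
#' ranks. For n of at most 12 retained pairs the two-sided p-value is exact,
#' enumerated over all 2^n sign assignments of the observed ranks (so ties
#' are handled conditionally); otherwise a tie-corrected normal
#' approximation with continuity correction is used. The matched
#' rank-biserial correlation is the signed-rank imbalance
#' (sum of positive ranks - sum of negative ranks) / (sum of all ranks),
#' in [-1, 1]: the relative proportion of positive over negative rank mass.
#'
#' @param pre,post Paired numeric vectors of equal length.
#' @param exact_max Largest n for which the exact enumeration is used.
#' @return One-row tibble: `test`, `statistic` (W), `z` (NA on the exact
#'   path), `p_raw`, `effect_size`, `effect_kind`, `n` (pairs retained),
#'   `note`.
#' @export
wilcoxon_rbc <- function(pre, post, exact_max = 12) {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(tibble::tibble(test = "wilcoxon_signed_rank", statistic = NA_real_,
                          z = NA_real_, p_raw = NA_real_, effect_size = NA_real_,
                          effect_kind = "rbc_matched", n = 0L,
                          note = "all differences zero: test undefined"))
  }
  if (n < 5L) {
    warning("fewer than 5 nonzero differences; the signed-rank test is weakly informative")
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  rbc <- (w_pos - w_neg) / sum(r)
  if (n <= exact_max) {
    # exact: distribution of W over all sign assignments of these ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(w_all <= w_pos), mean(w_all >= w_pos)))
    z <- NA_real_
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w_pos - mu) * 0.5
    z <- (w_pos - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(test = "wilcoxon_signed_rank", statistic = w_pos, z = z,
                 p_raw = p, effect_size = rbc, effect_kind = "rbc_matched",
                 n = n, note = "")
}

#' Mann-Whitney U test with rank-biserial correlation
#'
#' Two-sample rank test with mid-ranks for ties. When `n1 * n2` is at most
#' `exact_max` the two-sided p-value is exact, enumerated over all
#' `choose(n1 + n2, n1)` group labelings of the pooled ranks; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#' The rank-biserial effect size is `2U/(n1 n2) - 1`, in [-1, 1].
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_max Largest `n1 * n2` for which enumeration is used.
#' @return One-row tibble: `test`, `statistic` (U for the first sample),
#'   `z`, `p_raw`, `effect_size`, `effect_kind`, `n1`, `n2`, `note`.
#' @export
mann_whitney_rbc <- function(x, y, exact_max = 100) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  rbc <- 2 * u / (n1 * n2) - 1
  if (n1 * n2 <= exact_max) {
    sets <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
    z <- NA_real_
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    cc <- sign(u - mu) * 0.5
    z <- (u - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(test = "mann_whitney_u", statistic = u, z = z, p_raw = p,
                 effect_size = rbc, effect_kind = "rbc", n1 = n1, n2 = n2,
                 note = "")
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up false-discovery-rate adjustment, applied separately within each
#' family of tests (the correction is performed across dependent variables
#' and separately per test type and comparison; the family labels encode
#' that grouping).
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @param families Optional vector of family labels, recycled against
#'   `p_values`; `NULL` treats all p-values as one family.
#' @return Adjusted p-values in the input order.
#' @export
fdr_bh <- function(p_values, families = NULL) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  if (is.null(families)) return(stats::p.adjust(p_values, method = "BH"))
  stats::ave(p_values, families,
             FUN = function(p) stats::p.adjust(p, method = "BH"))
}

#' Holm adjustment within families
#'
#' Step-down familywise-error adjustment, same family semantics as
#' [fdr_bh()].
#'
#' @inheritParams fdr_bh
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p_values, families = NULL) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  if (is.null(families)) return(stats::p.adjust(p_values, method = "holm"))
  stats::ave(p_values, families,
             FUN = function(p) stats::p.adjust(p, method = "holm"))
}
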