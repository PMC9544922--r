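#' Statistical test results
#'
#' All tests in the package return a `mep_test` object: a list with
#' `method`, `statistic`, `df` (numeric vector), `p`, optionally
#' `effect_terms` (per-term statistic/df/p for factorial designs) and
#' `posthoc` (pairwise adjusted p-values).
#'
#' @name mep_test
NULL

new_mep_test <- function(method, statistic, df, p, effect_terms = NULL,
                         posthoc = NULL, extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df, p = p,
                   effect_terms = effect_terms, posthoc = posthoc), extra),
            class = "mep_test")
}

#' @export
print.mep_test <- function(x, ...) {
  cat(sprintf("<%s>\n", x$method))
  if (!is.null(x$effect_terms)) {
    for (nm in names(x$effect_terms)) {
      e <- x$effect_terms[[nm]]
      cat(sprintf("  %-12s F(%.4g, %.4g) = %.4g, p = %.4g\n",
                  paste0(nm, ":"), e$df[1], e$df[2], e$statistic, e$p))
    }
  } else {
    cat(sprintf("  statistic = %.6g, df = (%s), p = %.6g\n",
                x$statistic, paste(signif(x$df, 6), collapse = ", "), x$p))
  }
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects between/within decomposition: F is the ratio
#' of the between-group to the within-group mean square, with p from the
#' F distribution. If all groups share the same mean and there is no
#' within-group variance, F is defined as 0 with p = 1.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return A `mep_test` with fields `ms_within`, `df_within` and group
#'   summaries usable by [pairwise_posthoc()].
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least two values", call. = FALSE)
  }
  y <- unlist(groups)
  n_i <- vapply(groups, length, 1L)
  m_i <- vapply(groups, mean, 1)
  N <- length(y); g <- length(groups)
  gm <- mean(y)
  ss_between <- sum(n_i * (m_i - gm)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  df1 <- g - 1; df2 <- N - g
  if (ss_within <= 0) {
    if (ss_between <= 0) {
      Fv <- 0; p <- 1
    } else {
      Fv <- Inf; p <- 0
    }
  } else {
    Fv <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  new_mep_test("one-way ANOVA", Fv, c(df1, df2), p,
               extra = list(ms_within = if (df2 > 0) ss_within / df2 else NA_real_,
                            df_within = df2,
                            group_means = m_i, group_n = n_i,
                            group_labels = names(groups) %||%
                              paste0("g", seq_along(groups))))
}

#' Pairwise post-hoc comparisons after one-way ANOVA
#'
#' Three adjustment schemes:
#' * `"tukey"`: Tukey-Kramer studentized-range test, p from `ptukey`.
#' * `"bonferroni"`: pairwise pooled-variance t-tests with p multiplied
#'   by the number of comparisons (capped at 1).
#' * `"dunnett_mc"`: many-to-one comparisons against a control group,
#'   with the max-|t| null distribution obtained by seeded Monte Carlo
#'   (there is no closed form without multivariate-t machinery; the
#'   simulation error with the default 2e5 draws is about 0.003 on p).
#'
#' @param groups List of numeric vectors, one per group.
#' @param method `"tukey"`, `"bonferroni"` or `"dunnett_mc"`.
#' @param control Index of the control group (dunnett only, default 1).
#' @param nsim Monte Carlo draws for dunnett (default 2e5).
#' @param seed RNG seed for dunnett (default 1).
#' @return data.frame with columns `pair` and `p_adj`.
#' @export
pairwise_posthoc <- function(groups, method = c("tukey", "bonferroni", "dunnett_mc"),
                             control = 1L, nsim = 2e5, seed = 1L) {
  method <- match.arg(method)
  an <- one_way_anova(groups)
  msw <- an$ms_within; dfw <- an$df_within
  m <- an$group_means; n <- an$group_n
  labs <- an$group_labels
  g <- length(groups)
  if (method %in% c("tukey", "bonferroni")) {
    prs <- utils::combn(g, 2)
    m <- unname(m); n <- unname(n)
    p_adj <- vapply(seq_len(ncol(prs)), function(c_idx) {
      i <- prs[1, c_idx]; j <- prs[2, c_idx]
      if (method == "tukey") {
        q <- abs(m[i] - m[j]) / sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
        stats::ptukey(q, nmeans = g, df = dfw, lower.tail = FALSE)
      } else {
        tt <- abs(m[i] - m[j]) / sqrt(msw * (1 / n[i] + 1 / n[j]))
        min(1, 2 * stats::pt(tt, dfw, lower.tail = FALSE) * ncol(prs))
      }
    }, 1)
    return(data.frame(pair = paste(labs[prs[1, ]], labs[prs[2, ]], sep = " vs "),
                      p_adj = pmin(1, p_adj)))
  }
  # dunnett_mc: compare every non-control group to the control
  if (control < 1 || control > g) stop("invalid control group index", call. = FALSE)
  others <- setdiff(seq_len(g), control)
  t_obs <- vapply(others, function(i) {
    (m[i] - m[control]) / sqrt(msw * (1 / n[i] + 1 / n[control]))
  }, 1)
  tmax <- with_seed(seed, {
    # Null: group means ~ N(0, sigma^2/n_i), pooled s^2 ~ sigma^2 chi^2_df/df
    z <- matrix(stats::rnorm(nsim * g), nsim, g)
    z <- sweep(z, 2, sqrt(n), "/")
    s2 <- stats::rchisq(nsim, dfw) / dfw
    tmat <- vapply(others, function(i) {
      (z[, i] - z[, control]) / sqrt(s2 * (1 / n[i] + 1 / n[control]))
    }, numeric(nsim))
    apply(abs(as.matrix(tmat)), 1, max)
  })
  p_adj <- vapply(t_obs, function(tt) mean(tmax >= abs(tt)), 1)
  data.frame(pair = paste(labs[others], labs[control], sep = " vs "),
             p_adj = p_adj)
}

#' Split-plot (two-way repeated-measures) ANOVA
#'
#' The design behind the longitudinal group comparisons: a
#' between-subjects factor (treatment group) crossed with a
#' within-subjects factor (week), each animal measured at every week.
#' The decomposition is the classical split-plot one: the group effect
#' is tested against subjects-within-groups, and the time and
#' group-by-time effects against the within-subject residual.
#'
#' Sphericity of the within-subject covariance is corrected with the
#' Greenhouse-Geisser epsilon, computed from the pooled within-group
#' covariance of the repeated measures via orthonormal contrasts;
#' epsilon is always in `[1/(k-1), 1]` and multiplies the time and
#' interaction degrees of freedom (applied unconditionally when
#' `gg_correction = TRUE`, with no Mauchly pre-test).
#'
#' @param table data.frame with columns `animal_id`, `group`, `week`,
#'   `value`: a complete balanced panel (every animal at every week, no
#'   missing values).
#' @param gg_correction Apply the Greenhouse-Geisser correction to the
#'   within-subject terms (default TRUE).
#' @return A `mep_test` with `effect_terms` `Time`, `Treatment`,
#'   `Interaction` and field `epsilon`.
#' @export
rm_anova_split_plot <- function(table, gg_correction = TRUE) {
  need <- c("animal_id", "group", "week", "value")
  if (!all(need %in% names(table))) {
    stop("table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(table$value))) stop("missing values in panel", call. = FALSE)
  weeks <- sort(unique(table$week))
  animals <- unique(table$animal_id)
  k <- length(weeks); N <- length(animals)
  # balance check: every animal at every week, exactly once
  tab <- table(table$animal_id, table$week)
  if (any(tab != 1L)) stop("unbalanced panel: every animal needs exactly one value per week", call. = FALSE)
  grp_of <- tapply(table$group, table$animal_id, function(g) g[1])[animals]
  g_levels <- unique(grp_of)
  g <- length(g_levels)
  if (g < 2L) stop("need at least two groups", call. = FALSE)
  # subjects x weeks response matrix
  Y <- matrix(NA_real_, N, k, dimnames = list(animals, weeks))
  idx <- cbind(match(table$animal_id, animals), match(table$week, weeks))
  Y[idx] <- table$value

  gm <- mean(Y)
  m_subj <- rowMeans(Y)
  m_week <- colMeans(Y)
  m_grp <- tapply(m_subj, grp_of, mean)            # per-group subject means
  n_g <- table(grp_of)[names(m_grp)]
  # cell means group x week
  m_gw <- rowsum(Y, grp_of) / as.vector(table(grp_of)[sort(unique(grp_of))])
  m_gw <- m_gw[names(m_grp), , drop = FALSE]

  ss_between_subj <- k * sum((m_subj - gm)^2)
  ss_group <- k * sum(n_g * (m_grp - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_time <- N * sum((m_week - gm)^2)
  ss_int <- sum(as.vector(n_g) *
                  (m_gw - outer(as.vector(m_grp), rep(1, k)) -
                     outer(rep(1, nrow(m_gw)), m_week) + gm)^2)
  ss_total <- sum((Y - gm)^2)
  ss_err <- ss_total - ss_between_subj - ss_time - ss_int

  df_group <- g - 1; df_subj <- N - g
  df_time <- k - 1; df_int <- (g - 1) * (k - 1); df_err <- (N - g) * (k - 1)

  F_group <- (ss_group / df_group) / (ss_subj_within / df_subj)
  F_time <- (ss_time / df_time) / (ss_err / df_err)
  F_int <- (ss_int / df_int) / (ss_err / df_err)

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  Yc <- Y
  for (gl in names(m_grp)) {
    rows <- which(grp_of == gl)
    Yc[rows, ] <- sweep(Y[rows, , drop = FALSE], 2,
                        colMeans(Y[rows, , drop = FALSE]))
  }
  S <- crossprod(Yc) / (N - g)
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))                                  # orthonormal contrasts
  M <- t(C) %*% S %*% C
  lam_tr <- sum(diag(M))
  eps <- lam_tr^2 / ((k - 1) * sum(M * M))
  eps <- min(1, max(1 / (k - 1), eps))

  e_t <- if (gg_correction) eps else 1
  terms <- list(
    Time = list(statistic = F_time,
                df = c(e_t * df_time, e_t * df_err),
                p = stats::pf(F_time, e_t * df_time, e_t * df_err,
                              lower.tail = FALSE)),
    Treatment = list(statistic = F_group,
                     df = c(df_group, df_subj),
                     p = stats::pf(F_group, df_group, df_subj,
                                   lower.tail = FALSE)),
    Interaction = list(statistic = F_int,
                       df = c(e_t * df_int, e_t * df_err),
                       p = stats::pf(F_int, e_t * df_int, e_t * df_err,
                                     lower.tail = FALSE))
  )
  new_mep_test("two-way RM ANOVA (split-plot)",
               statistic = F_group, df = c(df_group, df_subj),
               p = terms$Treatment$p, effect_terms = terms,
               extra = list(epsilon = eps,
                            ss = c(group = ss_group, subj = ss_subj_within,
                                   time = ss_time, interaction = ss_int,
                                   error = ss_err)))
}

#' Exact two-sample Mann-Whitney U test
#'
#' Rank-sum test with the two-tailed p-value computed by exhaustive
#' enumeration of all assignments of the pooled observations to the two
#' groups: p is the fraction of assignments whose U deviates from its
#' null mean `n1*n2/2` by at least as much as the observed U. Ties are
#' handled with mid-ranks (the enumeration remains exact). Suitable for
#' the very small group sizes of terminal anatomy data (e.g. 5 vs 3,
#' where p-values are multiples of 1/56).
#'
#' @param x,y Numeric samples. The enumeration is guarded:
#'   `choose(n1+n2, n1)` must not exceed 1e6, otherwise an error directs
#'   to a normal approximation.
#' @return A `mep_test` with `statistic` = U (for `x`), `df` = c(n1, n2)
#'   and the exact two-tailed `p`.
#' @export
mann_whitney_exact <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty", call. = FALSE)
  if (choose(n1 + n2, n1) > 1e6) {
    stop("too many assignments to enumerate (choose(n, n1) > 1e6); ",
         "use a normal approximation for samples this large", call. = FALSE)
  }
  r <- rank(c(x, y))                       # mid-ranks for ties
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  dev <- abs(U_obs - mu)
  comb <- utils::combn(n1 + n2, n1)
  rank_offset <- n1 * (n1 + 1) / 2
  count <- 0L
  for (j in seq_len(ncol(comb))) {
    U <- sum(r[comb[, j]]) - rank_offset
    if (abs(U - mu) >= dev - 1e-12) count <- count + 1L
  }
  new_mep_test("exact Mann-Whitney U", U_obs, c(n1, n2),
               count / ncol(comb),
               extra = list(n_assignments = ncol(comb)))
}
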