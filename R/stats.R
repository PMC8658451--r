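#' Two-by-two mixed-design ANOVA from explicit sums of squares
#'
#' Split-plot ANOVA with one within-subject factor (condition, 2 levels) and
#' one between-subject factor (group, 2 levels). Sums of squares are computed
#' explicitly so each effect's partial eta squared has an unambiguous
#' denominator: the between-subjects error for the group effect, the
#' subject-by-condition error for condition and the interaction.
#'
#' @param values data.frame with columns `subject_id`, `condition`, `value`;
#'   every retained subject must have both condition values (incomplete
#'   subjects are dropped with a warning).
#' @param groups named vector or data.frame (`subject_id`, `group`) mapping
#'   subjects to exactly two groups.
#' @return data.frame with one row per effect (`condition`, `group`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
mixed_anova_2x2 <- function(values, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$subject_id))
  values$subject_id <- as.character(values$subject_id)
  conds <- sort(unique(values$condition))
  if (length(conds) != 2L) stop("need exactly 2 conditions")
  wide <- stats::reshape(values[, c("subject_id", "condition", "value")],
                         idvar = "subject_id", timevar = "condition",
                         direction = "wide")
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warning(sprintf("%d incomplete subject(s) dropped", sum(!complete)),
            call. = FALSE)
    wide <- wide[complete, ]
  }
  y <- as.matrix(wide[, -1, drop = FALSE])      # subjects x 2 conditions
  g <- factor(groups[wide$subject_id])
  if (nlevels(g) != 2L) stop("need exactly 2 groups")
  res <- split_plot_anova(y, g)
  res$effect <- c("condition", "interaction", "group")
  res[, c("effect", "F", "df1", "df2", "p", "partial_eta_sq")]
}

# Split-plot sums of squares for subjects x k within-levels, between factor g.
# Returns rows: within effect, within x group interaction, group.
split_plot_anova <- function(y, g, gg_correct = FALSE) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  subj_m <- rowMeans(y)
  lev_m <- colMeans(y)
  grp_m <- tapply(subj_m, g, mean)
  n_g <- tabulate(g)
  cell_m <- apply(y, 2L, function(col) tapply(col, g, mean))  # groups x k
  G <- nlevels(g)

  ss_between_subj <- k * sum((subj_m - grand)^2)
  ss_group <- k * sum(n_g * (grp_m - grand)^2)
  ss_subj_err <- ss_between_subj - ss_group
  df_subj_err <- n - G

  ss_within_lev <- n * sum((lev_m - grand)^2)
  ss_int <- sum(n_g * (cell_m - outer(grp_m, lev_m, "+") + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_within_err <- ss_total - ss_between_subj - ss_within_lev - ss_int
  df_within_err <- (n - G) * (k - 1)

  eps <- 1
  if (gg_correct && k > 2L) eps <- gg_epsilon(y, g)

  eff <- function(ss, df1, ss_err, df_err, apply_eps = FALSE) {
    f <- (ss / df1) / (ss_err / df_err)
    d1 <- df1; d2 <- df_err
    if (apply_eps) { d1 <- d1 * eps; d2 <- d2 * eps }
    data.frame(F = f, df1 = d1, df2 = d2,
               p = stats::pf(f, d1, d2, lower.tail = FALSE),
               partial_eta_sq = ss / (ss + ss_err))
  }
  out <- rbind(
    eff(ss_within_lev, k - 1, ss_within_err, df_within_err, apply_eps = TRUE),
    eff(ss_int, (k - 1) * (G - 1), ss_within_err, df_within_err, apply_eps = TRUE),
    eff(ss_group, G - 1, ss_subj_err, df_subj_err))
  out$gg_epsilon <- c(eps, eps, NA_real_)
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# k repeated measures, via orthonormal contrasts C:
# eps = tr(C S C')^2 / ((k-1) * tr((C S C')^2)), in (1/(k-1), 1].
gg_epsilon <- function(y, g = NULL) {
  k <- ncol(y)
  if (is.null(g)) {
    S <- stats::cov(y)
  } else {
    g <- factor(g)
    parts <- lapply(levels(g), function(l) {
      yy <- y[g == l, , drop = FALSE]
      (nrow(yy) - 1) * stats::cov(yy)
    })
    S <- Reduce(`+`, parts) / (nrow(y) - nlevels(g))
  }
  C <- t(qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE])
  V <- C %*% S %*% t(C)
  (sum(diag(V)))^2 / ((k - 1) * sum(V^2))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One within-subject factor with `k >= 2` levels and an optional
#' between-subject group factor. When `k > 2`, p-values for the within
#' effects use Greenhouse-Geisser epsilon-corrected degrees of freedom
#' (epsilon = 1 is reported at `k = 2`, where sphericity is trivial).
#' Subjects with any missing level are dropped listwise with a warning.
#'
#' @param y numeric matrix, subjects x within-levels (e.g. time bins).
#' @param groups optional factor/vector of group labels per subject row.
#' @return data.frame with rows for the within effect (`bin`), the
#'   `bin:group` interaction and `group` when groups are given; columns
#'   `effect`, `F`, `df1`, `df2` (epsilon-corrected for within effects),
#'   `p`, `partial_eta_sq`, `gg_epsilon`.
#' @export
rm_anova_gg <- function(y, groups = NULL) {
  y <- as.matrix(y)
  k <- ncol(y)
  if (k < 2L) stop("need at least 2 within-subject levels")
  keep <- stats::complete.cases(y)
  if (any(!keep)) {
    warning(sprintf("%d subject(s) with missing cells dropped", sum(!keep)),
            call. = FALSE)
    y <- y[keep, , drop = FALSE]
    if (!is.null(groups)) groups <- groups[keep]
  }
  if (is.null(groups)) {
    # single-group RM ANOVA: subjects are the blocking factor
    n <- nrow(y)
    grand <- mean(y)
    ss_lev <- n * sum((colMeans(y) - grand)^2)
    ss_subj <- k * sum((rowMeans(y) - grand)^2)
    ss_err <- sum((y - grand)^2) - ss_lev - ss_subj
    df1 <- k - 1; df2 <- (n - 1) * (k - 1)
    eps <- if (k > 2L) gg_epsilon(y) else 1
    f <- (ss_lev / df1) / (ss_err / df2)
    return(data.frame(effect = "bin", F = f, df1 = df1 * eps, df2 = df2 * eps,
                      p = stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE),
                      partial_eta_sq = ss_lev / (ss_lev + ss_err),
                      gg_epsilon = eps))
  }
  g <- factor(groups)
  res <- split_plot_anova(y, g, gg_correct = TRUE)
  res$effect <- c("bin", "bin:group", "group")
  res[, c("effect", "F", "df1", "df2", "p", "partial_eta_sq", "gg_epsilon")]
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure at level `q`: reject the `i` smallest p-values where `i`
#' is the largest rank with `p_(i) <= i q / m`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q accepted false-discovery rate (e.g. 0.10 or 0.05).
#' @return logical vector of rejections, aligned with `pvals`.
#' @export
bh_fdr <- function(pvals, q = 0.10) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Ordinary least-squares regression of connectivity on relative power
#'
#' @param pli numeric vector, one connectivity value per subject.
#' @param relpow numeric vector, matching relative power per subject.
#' @return list with `R` (signed correlation), `R2`, `p` (slope test),
#'   `slope`, `intercept`, `n`.
#' @export
regress_pli_on_power <- function(pli, relpow) {
  if (length(pli) != length(relpow)) stop("length mismatch")
  if (length(pli) < 3L) stop("need at least 3 subjects")
  if (stats::var(relpow) == 0) stop("zero-variance predictor")
  fit <- stats::lm(pli ~ relpow)
  sm <- summary(fit)
  list(R = unname(sign(stats::coef(fit)[2])) * sqrt(sm$r.squared),
       R2 = sm$r.squared,
       p = sm$coefficients[2, 4],
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(pli))
}

#' Stepwise multiple linear regression with p-value entry and removal
#'
#' Classical forward selection with backward elimination: at each step the
#' candidate with the smallest partial-F p-value enters if `p < p_in`; after
#' every entry, retained predictors with partial `p > p_out` are removed
#' (largest first); iterated to a fixed point. Each step reports the adjusted
#' R squared, the R-squared change and the F-change with its p-value. An
#' empty model (no candidate passes entry) is a valid result.
#'
#' @param y numeric outcome per subject.
#' @param X data.frame or matrix of candidate predictors (columns named).
#' @param p_in entry threshold (default 0.05).
#' @param p_out removal threshold (default 0.10).
#' @return list of class `stepwise_model`: `steps` data.frame (`action`,
#'   `predictor`, `adj_r2`, `delta_r2`, `f_change`, `p_change`), `selected`
#'   character vector, `se_estimate` residual standard error of the final
#'   model, `model` the final `lm` fit (or `NULL` for the empty model).
#' @export
stepwise_regression <- function(y, X, p_in = 0.05, p_out = 0.10) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    stop("candidate predictors must be named")
  n <- length(y)
  dat <- cbind(data.frame(.y = y), X)
  selected <- character(0)
  steps <- list()
  prev_r2 <- 0

  fit_for <- function(vars) {
    f <- if (length(vars) == 0L) ".y ~ 1" else
      paste(".y ~", paste(sprintf("`%s`", vars), collapse = " + "))
    stats::lm(stats::as.formula(f), data = dat)
  }
  partial_p <- function(fit, var) {
    cf <- summary(fit)$coefficients
    row <- match(sprintf("`%s`", var), rownames(cf))
    if (is.na(row)) row <- match(var, rownames(cf))
    cf[row, 4]
  }

  repeat {
    changed <- FALSE
    # forward: best candidate by partial F p-value
    remaining <- setdiff(names(X), selected)
    if (length(remaining) > 0L && n - length(selected) - 2L >= 1L) {
      cand_p <- vapply(remaining, function(v) {
        fit <- fit_for(c(selected, v))
        partial_p(fit, v)
      }, numeric(1))
      best <- names(which.min(cand_p))
      if (is.finite(cand_p[best]) && cand_p[best] < p_in) {
        fit0 <- fit_for(selected)
        selected <- c(selected, best)
        fit1 <- fit_for(selected)
        r2 <- summary(fit1)$r.squared
        an <- stats::anova(fit0, fit1)
        steps[[length(steps) + 1L]] <- data.frame(
          action = "add", predictor = best,
          adj_r2 = summary(fit1)$adj.r.squared,
          delta_r2 = r2 - prev_r2,
          f_change = an$F[2], p_change = an$`Pr(>F)`[2])
        prev_r2 <- r2
        changed <- TRUE
      }
    }
    # backward: drop worst retained predictor with p > p_out
    repeat {
      if (length(selected) == 0L) break
      fit <- fit_for(selected)
      ps <- vapply(selected, function(v) partial_p(fit, v), numeric(1))
      worst <- names(which.max(ps))
      if (ps[worst] > p_out) {
        fit1 <- fit_for(setdiff(selected, worst))
        r2 <- summary(fit1)$r.squared
        steps[[length(steps) + 1L]] <- data.frame(
          action = "remove", predictor = worst,
          adj_r2 = summary(fit1)$adj.r.squared,
          delta_r2 = r2 - prev_r2,
          f_change = NA_real_, p_change = ps[worst])
        selected <- setdiff(selected, worst)
        prev_r2 <- r2
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  final <- if (length(selected)) fit_for(selected) else NULL
  structure(list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(action = character(0), predictor = character(0),
                 adj_r2 = numeric(0), delta_r2 = numeric(0),
                 f_change = numeric(0), p_change = numeric(0)),
    selected = selected,
    se_estimate = if (is.null(final)) stats::sd(y) else summary(final)$sigma,
    model = final), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (nrow(x$steps) == 0L) {
    cat("<stepwise_model> empty model (no predictor passed entry)\n")
  } else {
    cat(sprintf("<stepwise_model> %d step(s); selected: %s; SE = %.4g\n",
                nrow(x$steps), paste(x$selected, collapse = " + "),
                x$se_estimate))
    print(x$steps, row.names = FALSE)
  }
  invisible(x)
}

#' One-way group contrast within a single condition
#'
#' Follow-up test after a significant interaction: a one-way ANOVA comparing
#' the two groups on per-subject scalars from one condition (F equals the
#' squared two-sample pooled t).
#'
#' @param values numeric vector of per-subject scalars.
#' @param groups group label per subject (exactly two groups, n >= 2 each).
#' @return data.frame row: `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
per_condition_group_test <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("need exactly 2 groups")
  if (any(tabulate(g) < 2L)) stop("need at least 2 subjects per group")
  grand <- mean(values)
  grp_m <- tapply(values, g, mean)
  n_g <- tabulate(g)
  ss_b <- sum(n_g * (grp_m - grand)^2)
  ss_w <- sum((values - grp_m[g])^2)
  df1 <- 1L; df2 <- length(values) - 2L
  f <- (ss_b / df1) / (ss_w / df2)
  data.frame(F = f, df1 = df1, df2 = df2,
             p = stats::pf(f, df1, df2, lower.tail = FALSE),
             partial_eta_sq = ss_b / (ss_b + ss_w))
}
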