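test_that("mixed ANOVA effects vanish when all cell means are equal", {
  # all four cell means equal 1; subject means and residuals vary
  vals <- data.frame(
    subject_id = rep(c("a", "b", "c", "d"), 2),
    condition = rep(c("baseline", "task"), each = 4),
    value = c(3, -1, 1, 1, 1, 1, 3, -1))
  groups <- c(a = "typ", b = "typ", c = "dys", d = "dys")
  an <- mixed_anova_2x2(vals, groups)
  expect_equal(an$F, rep(0, 3))
})

test_that("mixed ANOVA reproduces the aov Error-strata oracle", {
  set.seed(101)
  n <- 12
  subj <- sprintf("s%02d", 1:n)
  grp <- rep(c("typical", "dyslexic"), each = n / 2)
  base <- rnorm(n)
  vals <- data.frame(
    subject_id = rep(subj, 2),
    condition = rep(c("baseline", "task"), each = n),
    value = c(base + rnorm(n, 0, .4),
              base + 0.5 + ifelse(grp == "dyslexic", -0.6, 0) + rnorm(n, 0, .4)))
  mine <- mixed_anova_2x2(vals, setNames(grp, subj))

  d <- vals
  d$group <- factor(grp[match(d$subject_id, subj)])
  d$subject_id <- factor(d$subject_id)
  d$condition <- factor(d$condition)
  or <- summary(stats::aov(value ~ group * condition +
                             Error(subject_id / condition), data = d))
  between <- or[["Error: subject_id"]][[1]]
  within <- or[["Error: subject_id:condition"]][[1]]
  expect_equal(mine$F[mine$effect == "group"], between["group", "F value"],
               tolerance = 1e-8)
  expect_equal(mine$F[mine$effect == "condition"],
               within["condition", "F value"], tolerance = 1e-8)
  expect_equal(mine$F[mine$effect == "interaction"],
               within["group:condition", "F value"], tolerance = 1e-8)
  expect_equal(mine$p[mine$effect == "group"], between["group", "Pr(>F)"],
               tolerance = 1e-8)
})

test_that("a group shift moves the group effect, not the interaction", {
  set.seed(7)
  n <- 20
  subj <- sprintf("s%02d", 1:n)
  grp <- rep(c("typ", "dys"), each = n / 2)
  f_at_delta <- function(delta) {
    base <- rnorm(n)
    shift <- ifelse(grp == "dys", delta, 0)
    vals <- data.frame(
      subject_id = rep(subj, 2),
      condition = rep(c("baseline", "task"), each = n),
      value = c(base + shift + rnorm(n, 0, .3),
                base + shift + rnorm(n, 0, .3)))
    an <- mixed_anova_2x2(vals, setNames(grp, subj))
    c(group = an$F[an$effect == "group"],
      inter = an$F[an$effect == "interaction"])
  }
  res0 <- colMeans(t(replicate(60, f_at_delta(0))))
  res2 <- colMeans(t(replicate(60, f_at_delta(2))))
  expect_gt(res2["group"], 5 * res0["group"])
  expect_lt(res2["inter"], 4)  # interaction stays at null levels
})

test_that("partial eta squared is invariant to affine outcome rescaling", {
  set.seed(23)
  n <- 10
  subj <- sprintf("s%02d", 1:n)
  grp <- rep(c("typ", "dys"), each = 5)
  vals <- data.frame(subject_id = rep(subj, 2),
                     condition = rep(c("baseline", "task"), each = n),
                     value = rnorm(2 * n))
  a <- mixed_anova_2x2(vals, setNames(grp, subj))
  vals$value <- 3.7 * vals$value - 11
  b <- mixed_anova_2x2(vals, setNames(grp, subj))
  expect_equal(a$partial_eta_sq, b$partial_eta_sq, tolerance = 1e-10)
})

test_that("repeated-measures ANOVA matches its oracle and handles epsilon", {
  # k = 2 reduces to the paired contrast with epsilon 1
  set.seed(3)
  y <- cbind(rnorm(12), rnorm(12, 0.8))
  res <- rm_anova_gg(y)
  expect_equal(res$gg_epsilon, 1)
  tt <- t.test(y[, 1], y[, 2], paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # compound symmetry: epsilon near 1
  set.seed(19)
  subj_eff <- rnorm(80, 0, 2)
  y_cs <- matrix(rnorm(80 * 4), 80, 4) + subj_eff
  res_cs <- rm_anova_gg(y_cs)
  expect_gt(res_cs$gg_epsilon, 0.85)

  # rank-one within-subject structure: epsilon near the 1/(k-1) floor
  set.seed(29)
  w <- c(1, -1, 0, 0)
  y_ns <- outer(rnorm(40, 0, 3), w) + matrix(rnorm(160, 0, 1e-3), 40)
  res_ns <- rm_anova_gg(y_ns)
  expect_lt(res_ns$gg_epsilon, 0.40)
  expect_gte(res_ns$gg_epsilon, 1 / 3)

  # grouped version matches aov F statistics
  grp <- rep(c("a", "b"), each = 40)
  res_g <- rm_anova_gg(y_cs, groups = grp)
  dd <- data.frame(v = as.vector(y_cs),
                   s = factor(rep(1:80, 4)),
                   b = factor(rep(1:4, each = 80)),
                   g = factor(rep(grp, 4)))
  or <- summary(stats::aov(v ~ g * b + Error(s / b), data = dd))
  within <- or[["Error: s:b"]][[1]]
  expect_equal(res_g$F[res_g$effect == "bin"], within["b", "F value"],
               tolerance = 1e-8)
  expect_equal(res_g$F[res_g$effect == "bin:group"], within["g:b", "F value"],
               tolerance = 1e-8)
})

test_that("BH step-up matches the worked example and its brute-force form", {
  rej <- bh_fdr(c(0.001, 0.02, 0.03, 0.5), q = 0.10)
  expect_equal(rej, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), q = 0.10), rep(FALSE, 5))
  expect_identical(bh_fdr(numeric(0), 0.1), logical(0))

  set.seed(12)
  for (rep in 1:50) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p, 0.10), brute_force_bh(p, 0.10))
    expect_equal(bh_fdr(p, 0.05), brute_force_bh(p, 0.05))
    # rejections at the stricter level are a subset of the looser one
    expect_true(all(!bh_fdr(p, 0.05) | bh_fdr(p, 0.10)))
  }
})

test_that("PLI-power regression matches the closed-form Pearson quantities", {
  x <- c(1, 2, 3, 4, 5)
  exact <- suppressWarnings(regress_pli_on_power(2 * x, x))
  expect_equal(exact$R, 1)
  expect_equal(exact$R2, 1)

  set.seed(2)
  y <- c(0.3, 0.1, 0.45, 0.2, 0.5)
  r <- regress_pli_on_power(y, x)
  expect_equal(r$R, cor(x, y), tolerance = 1e-12)
  expect_equal(r$R2, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(r$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_error(regress_pli_on_power(y, rep(1, 5)), "zero-variance")
})

test_that("regression p-values are uniform under the null", {
  set.seed(77)
  ps <- replicate(1000, regress_pli_on_power(rnorm(100), rnorm(100))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("stepwise regression recovers exact and additive predictors", {
  set.seed(5)
  X <- data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  # outcome identical to one candidate (perfect-fit warnings are expected)
  sw <- suppressWarnings(stepwise_regression(X$x2 + 0, X))
  expect_equal(sw$selected, "x2")
  expect_gt(sw$steps$adj_r2[nrow(sw$steps)], 0.999)

  # two real predictors with small noise: both enter, delta R2 positive
  y <- X$x1 + X$x2 + rnorm(40, 0, 0.05)
  sw2 <- stepwise_regression(y, X)
  expect_setequal(sw2$selected, c("x1", "x2"))
  adds <- sw2$steps[sw2$steps$action == "add", ]
  expect_equal(nrow(adds), 2L)
  expect_true(all(adds$delta_r2 > 0))
  expect_true(all(adds$p_change < 0.05))
})

test_that("pure-noise candidates almost always yield the empty model", {
  # two independent null candidates: P(empty) ~ 0.95^2 ~ 0.90
  set.seed(92)
  empty <- replicate(500, {
    sw <- stepwise_regression(rnorm(30), data.frame(a = rnorm(30),
                                                    b = rnorm(30)))
    length(sw$selected) == 0L
  })
  expect_gte(mean(empty), 0.87)  # 3 binomial SD below the 0.9025 theory value
})

test_that("per-condition contrast is the squared two-sample t", {
  set.seed(8)
  v <- rnorm(20)
  g <- rep(c("typ", "dys"), each = 10)
  res <- per_condition_group_test(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # equal means give F ~ 0; F grows with the shift
  v0 <- rep(c(1, 2), 10)
  expect_lt(per_condition_group_test(v0, g)$F, 1e-20)
  f1 <- per_condition_group_test(v + ifelse(g == "dys", 1, 0), g)$F
  f3 <- per_condition_group_test(v + ifelse(g == "dys", 3, 0), g)$F
  expect_gt(f3, f1)
  expect_error(per_condition_group_test(v, rep("typ", 20)), "2 groups")
})
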