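make_table <- function(measures, dx, age = NULL, sex = NULL, severity = NULL) {
  n <- nrow(as.matrix(measures))
  subj <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                     age = age %||% rep(c(30, 50), length.out = n),
                     sex = sex %||% rep(c(0, 1), length.out = n),
                     dx = dx)
  if (!is.null(severity)) subj$severity <- severity
  regional_table(subj, as.matrix(measures))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("residualization reduces to the grand mean on a perfect covariate fit", {
  tab <- make_table(cbind(r1 = c(1, 2, 3)), dx = c(0, 0, 1),
                    age = c(1, 2, 3), sex = c(1, 1, 1))
  adj <- residualize(tab)
  expect_equal(unname(adj$table$measures[, 1]), c(2, 2, 2))
  expect_equal(adj$model$coefficients$b_age, 1)
  expect_equal(adj$model$coefficients$b_sex, 0)  # aliased, dropped
})

test_that("adjusted values are orthogonal to age and sex in every region", {
  set.seed(1)
  n <- 80
  tab <- make_table(matrix(rnorm(n * 5), n, 5) + runif(n, 20, 70) * 0.03,
                    dx = rep(c(0, 1), each = n / 2),
                    age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5))
  adj <- residualize(tab)$table
  expect_lt(max(abs(cor(adj$measures, tab$subjects$age))), 1e-8)
  expect_lt(max(abs(cor(adj$measures, tab$subjects$sex))), 1e-8)
})

test_that("residualization is a near no-op when no covariate effects exist", {
  set.seed(2)
  dev_at <- function(n) {
    tab <- make_table(matrix(rnorm(n * 3), n, 3), dx = rep(c(0, 1), each = n / 2),
                      age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5))
    max(abs(residualize(tab)$table$measures - tab$measures))
  }
  d_small <- dev_at(60); d_big <- dev_at(4000)
  expect_lt(d_big, d_small)    # estimation noise shrinks with n
  expect_lt(d_big, 0.2)
})

test_that("a fully constant covariate design is rejected", {
  tab <- make_table(cbind(r1 = c(1, 2, 3, 4)), dx = c(0, 0, 1, 1),
                    age = rep(40, 4), sex = rep(1, 4))
  expect_error(residualize(tab), "singular")
})

test_that("controls-only adjustment uses coefficients fitted on controls", {
  set.seed(3)
  n <- 400
  age <- runif(n, 20, 70); dx <- rep(c(0, 1), each = n / 2)
  x <- 0.1 * age + rnorm(n) - 0.5 * dx
  sex <- rbinom(n, 1, 0.5)
  tab <- make_table(cbind(r1 = x), dx = dx, age = age, sex = sex)
  adj <- residualize(tab, adjustment = "controls_only")
  ctrl <- dx == 0
  fit <- lm(x[ctrl] ~ age[ctrl] + sex[ctrl])
  expect_equal(adj$model$coefficients$b_age, unname(coef(fit)[2]),
               tolerance = 1e-10)
})

test_that("Cohen's d map matches the pooled-SD hand calculation", {
  tab <- make_table(cbind(r1 = c(1, 2, 3, 0, 1, 2)), dx = c(1, 1, 1, 0, 0, 0))
  em <- cohens_d_map(tab)
  expect_equal(em$d, 1)                       # means 2 vs 1, pooled SD 1
  expect_equal(em$t, 1 / sqrt(1 / 3 + 1 / 3))
  expect_equal(em$p, 2 * pt(-abs(em$t), df = 4))
  expect_equal(em$n_case, 3L)
  expect_equal(em$n_control, 3L)
})

test_that("identical group distributions yield d = 0, p = 1", {
  tab <- make_table(cbind(r1 = c(5, 6, 7, 5, 6, 7)), dx = c(1, 1, 1, 0, 0, 0))
  em <- cohens_d_map(tab)
  expect_equal(em$d, 0)
  expect_equal(em$p, 1)
})

test_that("degenerate regions yield NaN/NA with warnings", {
  tab <- make_table(cbind(r1 = c(2, 2, 0, 0)), dx = c(1, 1, 0, 0))
  expect_warning(em <- cohens_d_map(tab), "pooled SD is 0")
  expect_true(is.nan(em$d))
  tab2 <- make_table(cbind(r1 = c(2, 3, 0, 1)), dx = c(1, 0, 0, 0))
  expect_warning(em2 <- cohens_d_map(tab2), "fewer than 2")
  expect_true(is.na(em2$d))
})

test_that("d, t and p are invariant to positive rescaling of a measure", {
  set.seed(4)
  x <- rnorm(40)
  t1 <- make_table(cbind(r1 = x), dx = rep(c(0, 1), 20))
  t2 <- make_table(cbind(r1 = 7.3 * x), dx = rep(c(0, 1), 20))
  expect_equal(cohens_d_map(t1)[c("d", "t", "p")],
               cohens_d_map(t2)[c("d", "t", "p")])
})

test_that("a planted case deficit yields negative d", {
  set.seed(5)
  cfg <- sim_config(300, 300, 4, planted_d = -0.6, seed = 5)
  em <- cohens_d_map(residualize(simulate_regional_cohort(cfg))$table)
  expect_true(all(em$d < 0))
})

test_that("map summaries report mean, SD and extremes", {
  em <- structure(data.frame(region = c("a", "b", "c"),
                             d = c(-0.2, -0.3, -0.4),
                             p = c(0.1, 0.01, 0.001)),
                  class = c("effect_size_map", "data.frame"))
  sm <- summarize_map(em)
  expect_equal(sm$mean_d, -0.3)
  expect_equal(sm$sd_d, 0.1)
  expect_equal(as.character(sm$extremes$region[1]), "c")
  expect_error(summarize_map(data.frame(region = "a", d = 0.1)), "at least 2")
  expect_error(summarize_map(data.frame(region = "a", d = NaN)), "finite")
})

test_that("Bonferroni flags follow p < alpha / R with R from the map", {
  em <- data.frame(region = sprintf("r%02d", 1:33),
                   p = c(0.0014, 0.01, runif(31, 0.2, 1)))
  fl <- flag_significant(em, alpha = 0.05)
  expect_true(fl$significant_bonferroni[1])      # 0.0014 < 0.05/33
  expect_false(fl$significant_bonferroni[2])     # 0.01  > 0.05/33
  one <- flag_significant(data.frame(region = "a", p = 0.04))
  expect_true(one$significant_bonferroni)        # R = 1: plain alpha rule
  fdr <- flag_significant(em, method = "fdr")
  expect_true("significant_fdr" %in% names(fdr))
})

test_that("pooled adjustment removes an age confound that biases raw d", {
  set.seed(6)
  cfg <- sim_config(2000, 2000, 4, planted_d = -0.3, beta_age = 0.05,
                    age_shift_cases = 10, seed = 6)
  tab <- simulate_regional_cohort(cfg)
  raw <- cohens_d_map(tab)
  adj <- cohens_d_map(residualize(tab)$table)
  expect_gt(min(abs(raw$d - (-0.3))), 0.2)     # unadjusted: visibly biased
  expect_lt(mean(abs(adj$d - (-0.3))), 0.05)   # adjusted: recovered
})
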