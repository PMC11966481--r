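rvi_fixture <- function(n_case = 6, n_ctrl = 6, R = 5, seed = 1) {
  withr::with_seed(seed, {
    subj <- data.frame(subject_id = sprintf("s%02d", seq_len(n_case + n_ctrl)),
                       age = runif(n_case + n_ctrl, 20, 70),
                       sex = rbinom(n_case + n_ctrl, 1, 0.5),
                       dx = c(rep(1, n_case), rep(0, n_ctrl)))
    m <- matrix(rnorm((n_case + n_ctrl) * R), ncol = R,
                dimnames = list(NULL, sprintf("reg%02d", seq_len(R))))
    regional_table(subj, m)
  })
}

test_that("control reference uses controls only, with sample SD", {
  subj <- data.frame(subject_id = c("a", "b", "c"), age = c(1, 2, 3),
                     sex = c(0, 1, 0), dx = c(1, 0, 0))
  tab <- regional_table(subj, cbind(r1 = c(99, 0, 2)))
  ref <- build_control_reference(tab)
  expect_equal(ref$mu, 1)
  expect_equal(ref$sigma, sqrt(2))
  # cases cannot move the reference
  tab2 <- regional_table(subj, cbind(r1 = c(-50, 0, 2)))
  expect_equal(build_control_reference(tab2)$mu, 1)
})

test_that("degenerate control regions are excluded with a warning", {
  subj <- data.frame(subject_id = c("a", "b", "c"), age = c(1, 2, 3),
                     sex = c(0, 1, 0), dx = c(1, 0, 0))
  tab <- regional_table(subj, cbind(r1 = c(1, 5, 5), r2 = c(0, 1, 2)))
  expect_warning(ref <- build_control_reference(tab), "r1")
  expect_identical(ref$region, "r2")
  one_ctrl <- regional_table(subj[c(1, 2), ], cbind(r1 = c(1, 2)))
  expect_error(build_control_reference(one_ctrl), "at least 2 controls")
})

test_that("z-scoring against the reference is exact at the control sample", {
  tab <- rvi_fixture()
  ref <- build_control_reference(tab)
  z <- zscore_subjects(tab, ref)
  ctrl <- tab$subjects$dx == 0
  expect_equal(unname(colMeans(z[ctrl, ])), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(z[ctrl, ], 2, sd)), rep(1, 5), tolerance = 1e-10)
  # a subject at mu + sigma scores exactly 1 everywhere
  probe <- regional_table(
    data.frame(subject_id = "p", age = 30, sex = 0, dx = 1),
    matrix(ref$mu + ref$sigma, 1, dimnames = list(NULL, ref$region)))
  expect_equal(unname(zscore_subjects(probe, ref)[1, ]), rep(1, 5))
  bad <- regional_table(tab$subjects, tab$measures[, 1:3])
  expect_error(zscore_subjects(bad, ref), "absent")
})

test_that("RVI is the correlation with the template, with its sign logic", {
  tmpl <- setNames(c(-0.4, -0.1, -0.3, -0.2), sprintf("reg%02d", 1:4))
  z <- rbind(p1 = 2 * as.numeric(tmpl), p2 = -as.numeric(tmpl),
             p3 = rep(0.5, 4))
  colnames(z) <- names(tmpl)
  expect_warning(sc <- rvi_scores(z, tmpl), "degenerate")
  expect_equal(sc$rvi[1], 1)     # deviations proportional to the pattern
  expect_equal(sc$rvi[2], -1)    # anti-pattern
  expect_true(is.nan(sc$rvi[3])) # flat profile has no correlation
})

test_that("RVI is invariant to positive affine template changes, flips under negation", {
  set.seed(2)
  tmpl <- setNames(runif(8, -0.5, 0), sprintf("reg%02d", 1:8))
  z <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(NULL, names(tmpl)))
  base <- rvi_scores(z, tmpl)$rvi
  expect_equal(rvi_scores(z, 3 * tmpl + 0.7)$rvi, base)
  expect_equal(rvi_scores(z, -tmpl)$rvi, -base)
})

test_that("RVI matches regions by canonical name and reports mismatches", {
  tmpl <- setNames(c(-0.4, -0.1, -0.3), c("Reg 01", "REG-02", "reg_03"))
  expect_error(rvi_scores(matrix(rnorm(9), 3, 3,
                                 dimnames = list(NULL, c("a", "b", "c"))),
                          tmpl), "not present")
  z2 <- matrix(rnorm(9), 3, 3,
               dimnames = list(NULL, c("reg_01", "reg_02", "reg_03")))
  expect_silent(rvi_scores(z2, tmpl))
})

test_that("group contrast and symptom association behave on fixtures", {
  scores <- c(0.3, 0.4, 0.5, 0.3, 0.4, 0.5)
  dx <- c(1, 1, 1, 0, 0, 0)
  ct <- rvi_group_contrast(scores, dx)
  expect_equal(ct$cohen_d, 0)
  expect_error(rvi_group_contrast(c(0.1, 0.2, 0.3), c(1, 0, 0)), "per group")
  sev <- c(10, 20, 30, NA, NA, 15)
  rvi <- c(1, 2, 3, 0.5, 0.9, 1.5)
  as_ <- rvi_symptom_association(rvi, sev)
  expect_equal(as_$n, 4L)
  exact <- rvi_symptom_association(1:6, (1:6) * 2 + 3)
  expect_equal(exact$pearson_r, 1)
  expect_error(rvi_symptom_association(1:3, c(1, 2, 3)), "at least 4")
})

test_that("null z-profiles give mean RVI near zero", {
  set.seed(6)
  tmpl <- setNames(runif(34, -0.5, 0), sprintf("reg%02d", 1:34))
  z <- matrix(rnorm(2000 * 34), 2000, 34, dimnames = list(NULL, names(tmpl)))
  sc <- rvi_scores(z, tmpl)
  expect_lt(abs(mean(sc$rvi)), 0.02)
  expect_true(all(sc$rvi >= -1 & sc$rvi <= 1))
})

test_that("template-aligned cohorts separate cases from controls", {
  set.seed(7)
  tmpl_d <- runif(10, -0.5, 0)
  cfg <- sim_config(150, 150, 10, planted_d = tmpl_d, seed = 7)
  tab <- simulate_regional_cohort(cfg)
  adj <- residualize(tab)$table
  ref <- build_control_reference(adj)
  z <- zscore_subjects(adj, ref)
  sc <- rvi_scores(z, setNames(tmpl_d, tab$region_ids))
  ct <- rvi_group_contrast(sc, tab$subjects$dx)
  expect_gt(ct$cohen_d, 0)
})
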