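test_that("the node model recovers exact linear structure", {
  cov <- balanced_covariates(70, seed = 31)
  y <- 2 * cov$age
  fit <- suppressWarnings(fit_node_model(y, cov))  # exact fit warns in summary.lm
  expect_equal(fit$beta_group, 0, tolerance = 1e-10)

  # full coefficient recovery through the same design
  dat <- data.frame(y = y, group = as.integer(cov$group == "ALL"),
                    age = cov$age, sex = as.integer(cov$sex == "M"))
  lmfit <- lm(y ~ group + age + sex, data = dat)
  expect_equal(unname(coef(lmfit)["age"]), 2, tolerance = 1e-10)

  # constant y is flagged degenerate with p = 1
  fit0 <- fit_node_model(rep(3, nrow(cov)), cov)
  expect_true(fit0$degenerate)
  expect_equal(fit0$p_raw, 1)

  expect_error(fit_node_model(y[1:30], cov[1:30, ]), "at least 10")
})

test_that("robust group test holds its nominal type-I error under the null", {
  cov <- balanced_covariates(70, seed = 32)
  n_rep <- 800
  p <- withr::with_seed(33, vapply(seq_len(n_rep), function(r) {
    y <- 0.5 * cov$age + rnorm(nrow(cov))
    fit_node_model(y, cov)$p_raw
  }, numeric(1)))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("robust group test is unbiased for an injected effect", {
  cov <- balanced_covariates(70, seed = 34)
  g <- as.integer(cov$group == "ALL")
  est <- withr::with_seed(35, vapply(seq_len(400), function(r) {
    y <- g * 1 + rnorm(nrow(cov))
    fit_node_model(y, cov)$beta_group
  }, numeric(1)))
  expect_gt(mean(est), 0.9)
  expect_lt(mean(est), 1.1)
})

test_that("HC3 robust standard errors approach classical OLS errors under homoskedasticity", {
  cov <- balanced_covariates(1000, seed = 36)
  y <- withr::with_seed(37, 0.3 * cov$age + rnorm(nrow(cov)))
  fit <- fit_node_model(y, cov)
  dat <- data.frame(y = y, group = as.integer(cov$group == "ALL"),
                    age = cov$age, sex = as.integer(cov$sex == "M"))
  ols_se <- summary(lm(y ~ group + age + sex, data = dat))$coefficients["group", 2]
  expect_lt(abs(fit$robust_se / ols_se - 1), 0.05)
})

test_that("BH adjustment equals an independently coded step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.42, 7)), rep(0.42, 7))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::with_seed(38, {
    for (r in 1:200) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-15)
    }
  })
})

test_that("run_group_analysis yields one result per node x metric with valid fields", {
  h <- test_hierarchy()
  cfg <- sim_config(n_per_group = 12, seed = 39)
  res <- wmnet:::run_cohort_analysis(cfg, h)

  fr <- res$fine_results
  expect_equal(nrow(fr), 76 * 4)
  cr <- res$coarse_results
  expect_equal(nrow(cr), 24 * 4)
  for (tab in list(fr, cr)) {
    expect_true(all(tab$p_fdr >= tab$p_raw - 1e-15))
    expect_true(all(tab$p_raw >= 0 & tab$p_raw <= 1))
    expect_equal(tab$direction == "ALL>HC", tab$beta_group >= 0)
  }
  g <- glance(fr)
  expect_equal(g$n_tests, 304)

  # subject mismatch is an error
  cov_bad <- res$cohort$covariates
  cov_bad$subject_id[1] <- "ghost"
  expect_error(run_group_analysis(res$fine_metrics, cov_bad), "disagree")
})

test_that("frequency matching solves the toy case and respects the sex ratio", {
  mk <- function(ids, age, sex, group = "HC") {
    tibble::tibble(subject_id = ids, group = group, age = age, sex = sex)
  }
  cases <- mk(c("c1", "c2", "c3"), c(10, 10, 12), rep("M", 3), "ALL")
  pool <- mk(c("p1", "p2", "p3", "p4"), c(9.5, 10.8, 12.4, 20), rep("M", 4))
  sel <- frequency_match(cases, pool, age_tol = 1)
  expect_setequal(sel$subject_id, c("p1", "p2", "p3"))

  # identical pool: full one-to-one match
  cases2 <- mk(sprintf("c%d", 1:6), c(8, 9, 10, 11, 12, 13),
               rep(c("M", "F"), 3), "ALL")
  pool2 <- cases2; pool2$subject_id <- sprintf("p%d", 1:6); pool2$group <- "HC"
  sel2 <- frequency_match(cases2, pool2)
  expect_equal(nrow(sel2), 6)
  expect_equal(table(sel2$sex), table(cases2$sex))

  # disjoint sexes: empty result
  pool3 <- mk(sprintf("p%d", 1:4), c(10, 11, 12, 13), rep("F", 4))
  sel3 <- frequency_match(cases, pool3)
  expect_equal(nrow(sel3), 0)

  expect_error(frequency_match(cases, pool[0, ]), "empty")
})

test_that("matched selections always preserve the cases' sex ratio", {
  withr::with_seed(40, {
    for (r in 1:20) {
      n_case <- sample(6:20, 1)
      cases <- tibble::tibble(
        subject_id = sprintf("c%03d", seq_len(n_case)), group = "ALL",
        age = runif(n_case, 6, 20),
        sex = sample(c("M", "F"), n_case, replace = TRUE, prob = c(0.6, 0.4)))
      n_pool <- sample(10:40, 1)
      pool <- tibble::tibble(
        subject_id = sprintf("p%03d", seq_len(n_pool)), group = "HC",
        age = runif(n_pool, 6, 20),
        sex = sample(c("M", "F"), n_pool, replace = TRUE))
      sel <- frequency_match(cases, pool, seed = r)
      if (nrow(sel) == 0) next
      case_tab <- table(factor(cases$sex, levels = c("M", "F")))
      sel_tab <- table(factor(sel$sex, levels = c("M", "F")))
      # selected counts are an integer multiple of the reduced case ratio
      g <- case_tab[case_tab > 0]
      div <- Reduce(function(a, b) wmnet:::gcd2(a, b), g)
      unit <- case_tab / div
      t_units <- sel_tab[unit > 0] / unit[unit > 0]
      expect_true(all(abs(t_units - t_units[1]) < 1e-9))
      # every matched control is within tolerance of some same-sex case age
      for (k in seq_len(nrow(sel))) {
        expect_true(any(abs(cases$age[cases$sex == sel$sex[k]] - sel$age[k]) <= 1))
      }
    }
  })
})
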