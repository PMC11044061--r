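test_that("pooled t reproduces the published demographic comparisons", {
  age <- pooled_t_test(74.15, 7.53, 111, 64.46, 7.03, 75)
  expect_equal(age$t, 8.84, tolerance = 0.005 / 8.84)
  expect_equal(age$df, 184)
  expect_lt(age$p, 0.001)

  edu <- pooled_t_test(15.24, 3.31, 111, 16.05, 3.10, 75)
  expect_equal(edu$t, -1.68, tolerance = 0.005)
  expect_equal(edu$df, 184)

  same <- pooled_t_test(5, 1, 20, 5, 1, 20)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("pooled t from summaries equals t.test on raw data with those moments", {
  set.seed(31)
  x <- with_moments(rnorm(40), 10.3, 2.1)
  y <- with_moments(rnorm(25), 9.1, 2.6)
  ours <- pooled_t_test(mean(x), sd(x), 40, mean(y), sd(y), 25)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)

  ours_w <- welch_t_test(mean(x), sd(x), 40, mean(y), sd(y), 25)
  ref_w <- t.test(x, y)
  expect_equal(ours_w$t, unname(ref_w$statistic), tolerance = 1e-8)
  expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-8)
})

test_that("Welch df behaves per Satterthwaite", {
  # equal variances and n: df equals the pooled df
  eq <- welch_t_test(1, 2, 30, 0, 2, 30)
  expect_equal(eq$df, 58)
  # variance imbalance shrinks df below n1 + n2 - 2
  expect_lt(welch_t_test(0, 1, 50, 0, 4, 50)$df, 98)
  # days-between-MRI-and-assessment row: df 165.0 from the printed summaries
  days <- welch_t_test(14.01, 55.81, 111, 4.03, 25.47, 75)
  expect_equal(days$df, 165.0, tolerance = 0.1 / 165)
})

test_that("chi-square reproduces the published categorical comparisons", {
  sex <- pearson_chi_square(rbind(c(68, 43), c(51, 24)))
  expect_equal(sex$chi2, 0.88, tolerance = 0.005)
  expect_equal(sex$df, 1)

  dis <- pearson_chi_square(rbind(c(27, 84), c(62, 13)))
  expect_equal(dis$chi2, 61.05, tolerance = 0.005 / 61)
  expect_lt(dis$p, 0.001)

  sev <- pearson_chi_square(rbind(c(84, 12, 13, 2), c(13, 15, 27, 20)))
  expect_equal(sev$chi2, 67.49, tolerance = 0.005 / 67)
  expect_equal(sev$df, 3)

  scan <- pearson_chi_square(rbind(c(59, 32, 20), c(61, 14, 0)))
  expect_equal(scan$chi2, 20.89, tolerance = 0.005 / 20.89)
})

test_that("chi-square invariances and domain errors", {
  tab <- rbind(c(12, 30, 8), c(25, 9, 16))
  base <- pearson_chi_square(tab)$chi2
  expect_equal(pearson_chi_square(tab[2:1, ])$chi2, base)
  expect_equal(pearson_chi_square(tab[, c(2, 3, 1)])$chi2, base)
  # observed equal to expected gives exactly zero
  outer_tab <- outer(c(20, 30), c(10, 40)) / 50
  expect_equal(pearson_chi_square(outer_tab)$chi2, 0)
  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(pearson_chi_square(matrix(1, 1, 2)), "2 x 2")
})

test_that("partial eta squared follows its definition and domain", {
  expect_equal(partial_eta_squared(0, 5), 0)
  expect_equal(partial_eta_squared(1, 3), 0.25)
  expect_equal(partial_eta_squared(3, 1), 0.75)
  expect_error(partial_eta_squared(-1, 2), "non-negative")
  expect_error(partial_eta_squared(1, 0), "positive")
})

make_rm_metrics <- function(coh, y, network = "CCN",
                            densities = seq(0.25, 0.45, 0.05)) {
  do.call(rbind, lapply(densities, function(d)
    data.frame(subject_id = coh$subject_id, network = network, density = d,
               transitivity = y, global_efficiency = y,
               small_worldness = NA_real_, connected = TRUE,
               stringsAsFactors = FALSE)))
}

flat_cohort <- function(n_cell = 5) {
  data.frame(
    subject_id = sprintf("S%02d", seq_len(4 * n_cell)),
    diagnosis = rep(c("DAT", "bvFTD"), each = 2 * n_cell),
    disinhibition_present = rep(c(FALSE, TRUE, FALSE, TRUE), each = n_cell),
    disinhibition_severity = rep(c(0, 2, 0, 2), each = n_cell),
    age = 70, sex = "M", education = 16, cdr_sb = 5, tiv = 1.4e6,
    days_mri_npiq = 10, scanner = "Siemens", stringsAsFactors = FALSE
  )
}

test_that("rm_ancova matches a textbook two-way ANOVA sums-of-squares oracle", {
  set.seed(42)
  coh <- flat_cohort(5)
  y <- rnorm(20)
  fit <- rm_ancova(make_rm_metrics(coh, y), coh, "global_efficiency", "CCN",
                   covariates = character(0))
  # independent explicit SS decomposition for the balanced 2 x 2 design
  A <- factor(coh$diagnosis)
  B <- factor(coh$disinhibition_present)
  gm <- mean(y)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(A, B), mean)
  ssAB <- sum(5 * (cellm - gm)^2) - ssA - ssB
  ssE <- sum((y - ave(y, A, B))^2)
  eff <- fit$effects
  expect_equal(eff$F[eff$effect == "diagnosis"], (ssA / 1) / (ssE / 16),
               tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "disinhibition"], (ssB / 1) / (ssE / 16),
               tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "diagnosis:disinhibition"],
               (ssAB / 1) / (ssE / 16), tolerance = 1e-8)
  expect_equal(eff$df_den[1], 16L)
  # p values consistent with F and dfs; partial eta^2 consistent with SS
  expect_equal(eff$p, pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE))
  expect_equal(eff$partial_eta_sq[eff$effect == "diagnosis"],
               ssA / (ssA + ssE), tolerance = 1e-8)
  # contrast estimate reproduces the adjusted group difference
  expect_equal(eff$estimate[eff$effect == "disinhibition"],
               mean(y[B == TRUE]) - mean(y[B == FALSE]), tolerance = 1e-8)
})

test_that("a covariate orthogonal to the design leaves effect SS unchanged", {
  set.seed(7)
  coh <- flat_cohort(6)
  y <- rnorm(24)
  base <- rm_ancova(make_rm_metrics(coh, y), coh, "global_efficiency", "CCN",
                    covariates = character(0))
  # residualise a random covariate against the full design matrix
  # (including the response direction is irrelevant for orthogonality)
  mm <- model.matrix(~ factor(coh$diagnosis) * factor(coh$disinhibition_present))
  z <- rnorm(24)
  z <- z - mm %*% solve(crossprod(mm), crossprod(mm, z))
  coh$ortho <- as.numeric(z)
  with_cov <- rm_ancova(make_rm_metrics(coh, y), coh, "global_efficiency",
                        "CCN", covariates = "ortho")
  for (e in c("diagnosis", "disinhibition", "diagnosis:disinhibition")) {
    expect_equal(with_cov$effects$ss[with_cov$effects$effect == e],
                 base$effects$ss[base$effects$effect == e], tolerance = 1e-8)
  }
  expect_true(all(base$effects$partial_eta_sq >= 0 &
                    base$effects$partial_eta_sq <= 1))
})

test_that("rm_ancova validates its inputs", {
  coh <- flat_cohort(4)
  met <- make_rm_metrics(coh, rnorm(16))
  # unbalanced within-subject factor
  expect_error(rm_ancova(met[-1, ], coh, "global_efficiency", "CCN"),
               "unbalanced within-subject")
  # empty design cell
  coh2 <- coh
  coh2$disinhibition_present[coh2$diagnosis == "bvFTD"] <- TRUE
  coh2$disinhibition_severity[coh2$diagnosis == "bvFTD"] <- 1
  expect_error(rm_ancova(make_rm_metrics(coh2, rnorm(16)), coh2,
                         "global_efficiency", "CCN"),
               "empty design cell")
  expect_error(rm_ancova(met, coh, "no_such_metric", "CCN"), "no metric")
  expect_error(rm_ancova(met, coh, "global_efficiency", "XYZ"), "no rows")
  # missing covariate values
  coh3 <- coh
  coh3$age[2] <- NA
  expect_error(rm_ancova(make_rm_metrics(coh3, rnorm(16)), coh3,
                         "global_efficiency", "CCN",
                         covariates = "age"),
               "missing covariate")
})

test_that("degenerate-free interface: t-test input validation", {
  expect_error(pooled_t_test(1, 0, 10, 2, 1, 10), "positive")
  expect_error(pooled_t_test(1, 1, 1, 2, 1, 10), "n >= 2")
})
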