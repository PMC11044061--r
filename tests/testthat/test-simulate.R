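test_that("cohort generation matches the configured design", {
  cfg <- sim_config(n_dat = 111, n_bvftd = 75, seed = 7)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh), 186L)
  expect_equal(sum(coh$diagnosis == "DAT"), 111L)
  expect_equal(sum(coh$diagnosis == "bvFTD"), 75L)
  # structural invariants
  expect_true(all(coh$disinhibition_present == (coh$disinhibition_severity >= 1)))
  expect_true(all(coh$disinhibition_severity %in% 0:3))
  expect_true(all(coh$age > 0))
  expect_true(all(coh$tiv > 0))
  expect_true(all(coh$cdr_sb >= 0 & coh$cdr_sb <= 18))
  expect_equal(anyDuplicated(coh$subject_id), 0L)
})

test_that("degenerate disinhibition rate of zero yields a symptom-free cohort", {
  cfg <- small_cfg(seed = 3, disinhibition_rate = c(DAT = 0, bvFTD = 0))
  coh <- simulate_cohort(cfg)
  expect_false(any(coh$disinhibition_present))
  expect_true(all(coh$disinhibition_severity == 0))
})

test_that("identical configuration gives byte-identical cohorts and morphometry", {
  cfg <- small_cfg(n = 6, seed = 11)
  atl <- fixture_atlas()
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1, coh2)
  m1 <- simulate_morphometry(coh1, atl, cfg)
  m2 <- simulate_morphometry(coh2, atl, cfg)
  expect_identical(m1, m2)
})

test_that("subject records are independent of cohort size (sub-stream seeding)", {
  cfg_small <- small_cfg(n = 4, seed = 5)
  cfg_large <- small_cfg(n = 8, seed = 5)
  coh_small <- simulate_cohort(cfg_small)
  coh_large <- simulate_cohort(cfg_large)
  # first 4 DAT subjects identical in both cohorts
  expect_equal(coh_small[1:4, setdiff(names(coh_small), "scanner")],
               coh_large[1:4, setdiff(names(coh_large), "scanner")],
               ignore_attr = TRUE)
})

test_that("empirical covariate means stay within 3 standard errors at n >= 100", {
  cfg <- sim_config(n_dat = 120, n_bvftd = 120, seed = 13)
  coh <- simulate_cohort(cfg)
  for (g in c("DAT", "bvFTD")) {
    cv <- cfg$covariates[[g]]
    sub <- coh[coh$diagnosis == g, ]
    for (v in c("age", "education", "tiv", "days_mri_npiq")) {
      se <- cv$sd[v] / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[v]]) - cv$mean[v]), 3 * se,
                label = paste(g, v, "mean deviation"))
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_dat = 1), "at least 2 subjects")
  expect_error(sim_config(disinhibition_rate = c(DAT = -0.1, bvFTD = 0.5)),
               "rates must lie")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(effect_map = list(list(network = "CCN",
                                                 subset = "disinhibition",
                                                 attenuation = 1.5))),
               "attenuation")
  expect_error(
    simulate_morphometry(simulate_cohort(small_cfg()), fixture_atlas()[1:100, ],
                         small_cfg()),
    "structural error"
  )
})

test_that("morphometric tables have the declared shape and no degeneracy", {
  cfg <- small_cfg(n = 3, seed = 2)
  atl <- fixture_atlas()
  mor <- simulate_morphometry(simulate_cohort(cfg), atl, cfg)
  expect_length(mor, 6L)
  X <- mor[[1]]
  expect_equal(dim(X), c(360L, 7L))
  expect_equal(colnames(X), c("GM", "SA", "CT", "IC", "MC", "CI", "FI"))
  expect_equal(rownames(X), atl$region_id)
  expect_false(anyNA(X))
  expect_true(all(apply(X, 2, sd) > 0))
})

test_that("noise-free, latent-free subjects all share the archetype table", {
  cfg <- small_cfg(n = 2, seed = 9, latent_strength = 0, noise_sd = 1e-9)
  atl <- fixture_atlas()
  mor <- simulate_morphometry(simulate_cohort(cfg), atl, cfg)
  expect_equal(mor[[1]], mor[[2]], tolerance = 1e-6)
  expect_equal(mor[[1]], mor[[4]], tolerance = 1e-6)
})

test_that("at null, affected and unaffected subjects are exchangeable", {
  # attenuation 0: a two-sample t test on mean within-CCN similarity between
  # disinhibited and non-disinhibited subjects should be non-significant in
  # at least 90% of seeds
  atl <- fixture_atlas()
  idx <- network_nodes(atl, builtin_networks()$CCN)
  reject <- logical(20)
  for (s in 1:20) {
    cfg <- balanced_cfg(n = 25, seed = 100 + s,
                        effect_map = list(list(network = "CCN",
                                               subset = "disinhibition",
                                               attenuation = 0)))
    coh <- simulate_cohort(cfg)
    mor <- simulate_morphometry(coh, atl, cfg)
    mw <- vapply(mor, function(X) {
      W <- extract_subnetwork(build_msn(X), idx)
      mean(W[upper.tri(W)])
    }, 0)
    reject[s] <- t.test(mw[coh$disinhibition_present],
                        mw[!coh$disinhibition_present])$p.value < 0.05
  }
  expect_gte(mean(!reject), 0.90)
})

test_that("attenuation lowers mean within-network similarity for affected subjects", {
  atl <- fixture_atlas()
  idx <- network_nodes(atl, builtin_networks()$CCN)
  lower <- logical(20)
  for (s in 1:20) {
    cfg <- balanced_cfg(n = 50, seed = 200 + s)  # default: CCN attenuation 0.5
    coh <- simulate_cohort(cfg)
    mor <- simulate_morphometry(coh, atl, cfg)
    mw <- vapply(mor, function(X) {
      W <- extract_subnetwork(build_msn(X), idx)
      mean(W[upper.tri(W)])
    }, 0)
    lower[s] <- mean(mw[coh$disinhibition_present]) <
      mean(mw[!coh$disinhibition_present])
  }
  expect_gte(mean(lower), 0.95)
})

test_that("expected within-network weight is monotone in attenuation", {
  atl <- fixture_atlas()
  idx <- network_nodes(atl, builtin_networks()$CCN)
  mean_w <- function(atten, seed) {
    cfg <- small_cfg(n = 3, seed = seed,
                     disinhibition_rate = c(DAT = 1, bvFTD = 1),
                     effect_map = list(list(network = "CCN",
                                            subset = "disinhibition",
                                            attenuation = atten)))
    mor <- simulate_morphometry(simulate_cohort(cfg), atl, cfg)
    mean(vapply(mor, function(X) {
      W <- extract_subnetwork(build_msn(X), idx)
      mean(W[upper.tri(W)])
    }, 0))
  }
  # averaged over 20 seeds; attenuation shares each seed's noise draws, so the
  # comparison is paired
  m0 <- mean(vapply(1:20, function(s) mean_w(0.0, 300 + s), 0))
  m5 <- mean(vapply(1:20, function(s) mean_w(0.5, 300 + s), 0))
  m9 <- mean(vapply(1:20, function(s) mean_w(0.9, 300 + s), 0))
  expect_gt(m0, m5)
  expect_gt(m5, m9)
})
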