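state_mass <- function(...) {
  # probability vector over (U, HE, FE, HI, FI, FM)
  p <- setNames(rep(0, 6), c("U", "HE", "FE", "HI", "FI", "FM"))
  args <- list(...)
  p[names(args)] <- unlist(args)
  p
}

test_that("simulation configs validate their probabilities", {
  expect_s3_class(msap_sim_config(), "msap_sim_config")
  expect_error(msap_sim_config(p_dm_cg = 1.2), "\\[0, 1\\]")
  expect_error(msap_sim_config(state_probs = rep(0.2, 6)), "summing to 1")
  expect_error(msap_sim_config(state_probs = rep(1 / 5, 5)), "6 non-negative")
  expect_error(msap_sim_config(n_markers = 0), "positive")
})

test_that("simulations are bit-reproducible under a fixed seed", {
  cfg <- msap_sim_config(n_markers = 150, n_samples = 2, seed = 123)
  s1 <- simulate_msap(cfg)
  s2 <- simulate_msap(cfg)
  expect_identical(s1$bundle, s2$bundle)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_msap(msap_sim_config(n_markers = 150, n_samples = 2, seed = 124))
  expect_false(identical(s1$bundle, s3$bundle))
})

test_that("zero change rates preserve the control tracks", {
  sim <- simulate_msap(n_markers = 200, n_samples = 2,
                       p_dm_cg = 0, p_dm_chg = 0, p_dnm_cg = 0, p_dnm_chg = 0,
                       seed = 3)
  expect_identical(sim$bundle$stressed_hpa, sim$bundle$control_hpa)
  expect_identical(sim$bundle$stressed_msp, sim$bundle$control_msp)
  expect_equal(sum(sim$truth[c("DM", "DNM"), ]), 0)
  expect_equal(sim$rejection_rate, 0)
})

test_that("deterministic corner configurations yield the expected codes", {
  # all sites unmethylated, no de novo methylation: every marker is 1111
  sim <- simulate_msap(n_markers = 100, n_samples = 1,
                       state_probs = state_mass(U = 1),
                       p_dnm_cg = 0, p_dnm_chg = 0, seed = 5)
  cc <- extract_codes(sim$bundle)
  expect_equal(cc["1111", 1], 100L)

  # fully methylated sites demethylating with certainty: FM -> U, code 0011
  sim <- simulate_msap(n_markers = 100, n_samples = 1,
                       state_probs = state_mass(FM = 1),
                       p_dm_cg = 1, p_dm_chg = 1,
                       p_dnm_cg = 0, p_dnm_chg = 0, seed = 5)
  cc <- extract_codes(sim$bundle)
  expect_equal(cc["0011", 1], 100L)
  expect_equal(sim$truth[["DM", 1]], 400L)
  expect_equal(sim$truth[["DM_CG", 1]], 200L)
})

test_that("impossible rejection settings fail loudly instead of spinning", {
  # from HE, forcing both an external demethylation and an external de novo
  # methylation always lands outside the admissible states
  expect_error(
    simulate_msap(n_markers = 5, n_samples = 1,
                  state_probs = state_mass(HE = 1),
                  p_dm_chg = 1, p_dnm_chg = 1, seed = 1),
    "rejection sampling")
})

test_that("simulate -> extract -> quantify closes and satisfies identities", {
  sim <- simulate_msap(n_markers = 400, n_samples = 3, seed = 17)
  expect_gte(sim$rejection_rate, 0)
  expect_lt(sim$rejection_rate, 1)
  expect_equal(colSums(sim$truth[c("DM", "DNM", "MSP", "NMSP"), ]),
               colSums(matrix(4L * 400L, 1, 3,
                              dimnames = list(NULL, colnames(sim$truth)))))
  fit <- msap(sim$bundle)
  tot <- fit$totals
  expect_equal(tot["M", ], tot["DNM", ] + tot["MSP", ])
  expect_equal(tot["NM", ], tot["DM", ] + tot["NMSP", ])
  expect_equal(tot["DM", ], tot["DM_CG", ] + tot["DM_CHG", ])
  expect_equal(tot["DNM", ], tot["DNM_CG", ] + tot["DNM_CHG", ])
  rep <- recovery_report(sim, fit)
  expect_equal(nrow(rep), 8L * 3L)
  expect_true(all(rep$true_pct >= 0 & rep$true_pct <= 100))
})

test_that("states U/HE with zero change rates estimate exactly zero change", {
  # only codes 1111 and 1010 can arise, and neither carries change events
  sim <- simulate_msap(n_markers = 500, n_samples = 2,
                       state_probs = state_mass(U = 0.6, HE = 0.4),
                       p_dm_cg = 0, p_dm_chg = 0, p_dnm_cg = 0, p_dnm_chg = 0,
                       seed = 29)
  fit <- msap(sim$bundle)
  expect_equal(unname(fit$characteristics["DM%", ]), c(0, 0))
  expect_equal(unname(fit$characteristics["DNM%", ]), c(0, 0))
})

test_that("mixed-state controls show the documented baseline bias", {
  sim <- simulate_msap(n_markers = 500, n_samples = 1,
                       state_probs = state_mass(U = 0.4, HI = 0.3, FM = 0.3),
                       p_dm_cg = 0, p_dm_chg = 0, p_dnm_cg = 0, p_dnm_chg = 0,
                       seed = 31)
  fit <- msap(sim$bundle)
  expect_equal(sum(sim$truth[c("DM", "DNM"), ]), 0)   # nothing truly changed
  expect_gt(fit$characteristics["DM%", 1], 0)          # yet the model scores change
  expect_gt(fit$characteristics["DNM%", 1], 0)
})

test_that("estimated context rates increase with their simulation rate", {
  mean_est <- sapply(c(0.02, 0.12), function(rate) {
    vals <- sapply(1:2, function(s) {
      sim <- simulate_msap(n_markers = 2000, n_samples = 1,
                           p_dm_cg = rate, seed = 1000 + s)
      msap(sim$bundle)$characteristics["DM_CG%", 1]
    })
    mean(vals)
  })
  expect_lt(mean_est[1], mean_est[2])
})

test_that("recovery_report rejects mismatched samples", {
  sim <- simulate_msap(n_markers = 50, n_samples = 2, seed = 2)
  fit <- msap(extract_codes(sim$bundle)[, 1, drop = FALSE])
  expect_error(recovery_report(sim, fit), "samples.*differ")
})
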