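test_that("simulated responses saturate and symmetrise where they must", {
  inst <- make_instrument(2, max_category = 1L)
  cfg <- simulation_config(n_persons = 200, theta_mean = 10, theta_sd = 1e-6,
                           instrument = inst,
                           item_steps = list(i01 = 0, i02 = 0), seed = 1)
  d <- simulate_pcm_responses(cfg)
  expect_true(all(d$responses$values == 1L))   # prob ~ 1 at +10 logits

  inst3 <- make_instrument(2, max_category = 2L)
  n <- 30000
  cfg3 <- simulation_config(n_persons = n, theta_mean = 0, theta_sd = 1e-9,
                            instrument = inst3,
                            item_steps = list(i01 = c(0, 0), i02 = c(0, 0)),
                            seed = 2)
  d3 <- simulate_pcm_responses(cfg3)
  freq <- tabulate(d3$responses$values[, 1] + 1L, 3) / n
  se3 <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 3 * se3))
})

test_that("empirical category frequencies track the analytic probabilities", {
  inst <- make_instrument(2)
  steps <- list(i01 = c(-1.2, -0.3, 0.4, 1.5), i02 = c(-0.5, 0, 0.5, 1))
  cfg <- simulation_config(n_persons = 10000, theta_mean = 0.3,
                           theta_sd = 1e-9, instrument = inst,
                           item_steps = steps, seed = 7)
  d <- simulate_pcm_responses(cfg)
  for (id in c("i01", "i02")) {
    emp <- tabulate(d$responses$values[, id] + 1L, 5) / 10000
    ana <- pcm_category_probs(0.3, steps[[id]])
    expect_lt(max(abs(emp - ana)), 0.02)
  }
})

test_that("non-finite generating steps are rejected", {
  inst <- make_instrument(2)
  expect_error(simulation_config(instrument = inst,
                                 item_steps = list(i01 = c(1, 2, 3, Inf),
                                                   i02 = rep(0, 4))),
               "non-finite")
})

test_that("all stochastic outputs are bit-reproducible under a seed", {
  cfg <- simulation_config(n_persons = 60, seed = 123)
  d1 <- simulate_pcm_responses(cfg)
  d2 <- simulate_pcm_responses(cfg)
  expect_identical(d1$responses$values, d2$responses$values)
  expect_identical(d1$theta, d2$theta)
  rule <- default_rule_for_tests()
  s1 <- simulate_clinician_survey(cfg, rule)
  s2 <- simulate_clinician_survey(cfg, rule)
  expect_identical(s1$threshold, s2$threshold)
  tot <- raw_total_score(d1$responses)
  expect_identical(simulate_referrals(tot, cfg),
                   simulate_referrals(tot, cfg))
})

test_that("clinician survey recovery: noiseless identity and majority vote", {
  inst <- absst_instrument()
  rule <- pivot_rule(inst$item_id,
                     pmin(3L, inst$max_category), endorsement_pct = 100)
  cfg0 <- simulation_config(jitter_prob = 0, relevance_prob = 1, seed = 9)
  sv <- simulate_clinician_survey(cfg0, rule)
  rec <- aggregate_thresholds(sv)
  expect_equal(rec$flag_threshold, rule$flag_threshold)
  expect_equal(rec$endorsement_pct, rep(100, nrow(inst)))

  # response-rate bookkeeping: 23 of 28 expected; exact under the seed
  expect_lte(length(sv$clinicians), 28L)
  expect_identical(length(simulate_clinician_survey(cfg0, rule)$clinicians),
                   length(sv$clinicians))

  # majority vote over many jittered surveys recovers the true rule
  votes <- matrix(NA_integer_, 1000, nrow(inst))
  for (r in 1:1000) {
    cfg <- simulation_config(jitter_prob = 0.2, relevance_prob = 1,
                             seed = 5000 + r)
    votes[r, ] <- aggregate_thresholds(
      simulate_clinician_survey(cfg, rule))$flag_threshold
  }
  modal <- apply(votes, 2, function(v) {
    tab <- table(v); as.integer(names(tab)[which.max(tab)])
  })
  expect_equal(modal, rule$flag_threshold)
})

test_that("referral generation follows its logistic link", {
  cfg0 <- simulation_config(referral_intercept = 0, referral_slope = 0,
                            seed = 10)
  scores <- stats::setNames(sample(0:32, 5000, replace = TRUE),
                            sprintf("P%04d", 1:5000))
  lab <- simulate_referrals(scores, cfg0)
  expect_lt(abs(mean(lab$referred) - 0.5), 0.03)   # b = 0: rate ~ 1/2

  # a near-infinite slope pivoting at 5.5 gives deterministic labels
  cfg_inf <- simulation_config(referral_intercept = -5.5 * 200,
                               referral_slope = 200, seed = 11)
  lab2 <- simulate_referrals(scores, cfg_inf)
  expect_identical(lab2$referred, unname(scores >= 6))

  # slope recovery: across replicate simulations the estimate falls within
  # 2 SE of the generating slope in (at least) the expected 95% share
  hits <- vapply(1:5, function(s) {
    cfg_b <- simulation_config(seed = 12 + s)   # a = -4, b = 0.3
    lab3 <- simulate_referrals(scores, cfg_b)
    lg <- fit_logistic(as.numeric(scores), lab3)
    abs(lg$slope - cfg_b$referral_slope) < 2 * lg$se
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("the cut-point fixture is the unique allocation implied in print", {
  fx <- table3_fixture()
  expect_length(fx$scores, 151L)
  expect_equal(sum(fx$labels$referred), 49L)
  expect_equal(sum(!fx$labels$referred), 102L)

  # brute-force: the printed sensitivities/specificities (2 dp) pin down
  # the at-or-above-cut counts uniquely given the group sizes
  printed_se <- c(`21` = 2.04, `9` = 69.39, `6` = 85.71, `4` = 93.88,
                  `1` = 97.96)
  printed_sp <- c(`21` = 100.00, `9` = 96.08, `6` = 93.14, `4` = 68.63,
                  `1` = 14.71)
  for (cut in c(21, 9, 6, 4, 1)) {
    k_se <- which(round(100 * (0:49) / 49, 2) == printed_se[as.character(cut)]) - 1
    expect_length(k_se, 1L)
    expect_equal(sum(fx$scores[fx$labels$referred] >= cut), k_se)
    k_sp <- which(round(100 * (0:102) / 102, 2) ==
                    printed_sp[as.character(cut)]) - 1
    expect_length(k_sp, 1L)
    expect_equal(sum(fx$scores[!fx$labels$referred] < cut), k_sp)
  }
  # spot checks at the extreme cuts
  expect_equal(sum(fx$scores[fx$labels$referred] >= 21), 1L)
  expect_equal(sum(fx$scores[!fx$labels$referred] >= 21), 0L)
  expect_equal(sum(fx$scores[fx$labels$referred] >= 6), 42L)
  expect_equal(sum(fx$scores[!fx$labels$referred] >= 6), 7L)
})
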