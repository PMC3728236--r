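test_that("category probabilities match closed forms and sum to one", {
  # dichotomous: logistic midpoint and ln(3) offset
  expect_equal(pcm_category_probs(0, 0), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(pcm_category_probs(log(3), 0), c(0.25, 0.75),
               tolerance = 1e-12)
  # three categories, both steps at 0, theta 0: uniform
  expect_equal(pcm_category_probs(0, c(0, 0)), rep(1 / 3, 3),
               tolerance = 1e-12)
  # random draws: sum to 1, match the direct-summation oracle
  set.seed(4)
  for (r in 1:25) {
    th <- rnorm(1, 0, 2)
    d <- rnorm(sample(1:5, 1), 0, 1.5)
    p <- pcm_category_probs(th, d)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, oracle_pcm_probs(th, d), tolerance = 1e-12)
  }
  # numerically stable far into the tails
  expect_equal(unname(pcm_category_probs(300, c(0, 0))[3]), 1,
               tolerance = 1e-12)
  expect_equal(unname(pcm_category_probs(-300, c(0, 0))[1]), 1,
               tolerance = 1e-12)
})

test_that("expected score and variance match the direct-sum oracle", {
  expect_equal(pcm_expected(0, c(0, 0)),
               list(E = 1, W = 2 / 3), tolerance = 1e-12)
  # limits
  lo <- pcm_expected(-50, c(0, 0))
  expect_equal(lo$E, 0, tolerance = 1e-12)
  expect_equal(lo$W, 0, tolerance = 1e-12)
  set.seed(5)
  for (r in 1:25) {
    th <- rnorm(1, 0, 2); d <- rnorm(sample(1:5, 1), 0, 1.5)
    p <- oracle_pcm_probs(th, d)
    cats <- 0:length(d)
    E <- sum(cats * p); W <- sum((cats - E)^2 * p)
    got <- pcm_expected(th, d)
    expect_equal(got$E, E, tolerance = 1e-12)
    expect_equal(got$W, W, tolerance = 1e-12)
    expect_true(got$E >= 0 && got$E <= length(d) && got$W >= 0)
  }
})

test_that("higher theta stochastically raises the response category", {
  set.seed(6)
  for (r in 1:10) {
    d <- sort(rnorm(4, 0, 1))
    th <- sort(rnorm(2, 0, 2))
    p_lo <- pcm_category_probs(th[1], d)
    p_hi <- pcm_category_probs(th[2], d)
    # survivor function ordering: P(X >= k) increases with theta
    s_lo <- rev(cumsum(rev(p_lo)))
    s_hi <- rev(cumsum(rev(p_hi)))
    expect_true(all(s_hi - s_lo >= -1e-12))
  }
})

test_that("JMLE matches the grid-search maximiser on a dichotomous toy", {
  # two dichotomous items; patterns (1,0) x3 and (0,1) x1 (scores of 0 or 2
  # are extreme and excluded); grid-search the same joint likelihood over
  # the centred parameterisation delta = (d, -d), common theta t.
  X <- rbind(matrix(c(1L, 0L), 3, 2, byrow = TRUE), c(0L, 1L),
             c(0L, 0L), c(1L, 1L))
  rm <- make_responses(X, max_category = 1L)
  fit <- fit_pcm(rm, run_config(jmle_tol = 1e-7, jmle_max_iter = 500))
  expect_true(fit$converged)
  expect_setequal(fit$dropped_persons, c("P005", "P006"))

  loglik <- function(t, d) {
    p1 <- stats::plogis(t - d); p2 <- stats::plogis(t + d)
    3 * (log(p1) + log(1 - p2)) + (log(1 - p1) + log(p2))
  }
  t_grid <- seq(-3, 3, by = 0.05); d_grid <- seq(-3, 3, by = 0.05)
  for (pass in 1:3) {
    ll <- outer(t_grid, d_grid, Vectorize(loglik))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    t_hat <- t_grid[ix[1]]; d_hat <- d_grid[ix[2]]
    step <- t_grid[2] - t_grid[1]
    t_grid <- seq(t_hat - step, t_hat + step, length.out = 81)
    d_grid <- seq(d_hat - step, d_hat + step, length.out = 81)
  }
  expect_equal(unname(fit$steps[["i01"]]), d_hat, tolerance = 1e-3)
  expect_equal(unname(fit$steps[["i02"]]), -d_hat, tolerance = 1e-3)
  expect_equal(unname(fit$theta[["P001"]]), t_hat, tolerance = 1e-3)
  # closed form for this design: P(X1=1) = 3/4, P(X2=1) = 1/4 at theta 0
  expect_equal(unname(fit$steps[["i01"]]), -log(3), tolerance = 1e-3)
})

test_that("identical response columns get equal step estimates", {
  set.seed(12)
  col <- sample(0:4, 60, replace = TRUE)
  other <- sample(0:4, 60, replace = TRUE)
  rm <- make_responses(cbind(col, col, other))
  fit <- fit_pcm(rm)
  expect_equal(fit$steps[["i01"]], fit$steps[["i02"]], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("the fit is invariant to person and item reordering", {
  set.seed(13)
  cfg <- simulation_config(n_persons = 80, theta_mean = 0, theta_sd = 1.5,
                           instrument = make_instrument(4),
                           item_steps = default_item_steps(
                             make_instrument(4)), seed = 8)
  rm <- simulate_pcm_responses(cfg)$responses
  fit <- fit_pcm(rm)
  perm_p <- sample(nrow(rm$values))
  perm_i <- c(3, 1, 4, 2)
  rm2 <- response_matrix(rm$values[perm_p, perm_i], rm$items[perm_i, ])
  fit2 <- fit_pcm(rm2)
  expect_equal(fit2$steps[names(fit$steps)], fit$steps, tolerance = 1e-6)
  expect_equal(fit2$theta[names(fit$theta)], fit$theta, tolerance = 1e-6)
})

test_that("identification constraint and SE contracts hold", {
  set.seed(14)
  inst <- make_instrument(5)
  cfg <- simulation_config(n_persons = 120, theta_mean = 0, theta_sd = 1.5,
                           instrument = inst,
                           item_steps = default_item_steps(inst), seed = 21)
  fit <- fit_pcm(simulate_pcm_responses(cfg)$responses)
  expect_equal(mean(vapply(fit$steps, mean, numeric(1))), 0,
               tolerance = 1e-8)
  expect_true(all(unlist(fit$step_se) > 0))
  expect_true(all(fit$theta_se > 0))
})

test_that("extreme scores are dropped and given extrapolated measures", {
  X <- rbind(c(0L, 0L, 0L), c(4L, 4L, 4L),
             matrix(sample(0:4, 30, replace = TRUE), 10, 3))
  set.seed(15)
  X[3:12, ] <- matrix(sample(1:3, 30, replace = TRUE), 10, 3)
  rm <- make_responses(X)
  fit <- fit_pcm(rm)
  expect_setequal(fit$dropped_persons, c("P001", "P002"))
  # extrapolated measures bracket the estimated ones
  expect_lt(fit$theta[["P001"]], min(fit$theta[!fit$extreme]))
  expect_gt(fit$theta[["P002"]], max(fit$theta[!fit$extreme]))
  # the extrapolation solves expected score = 0.3 / max - 0.3
  E0 <- sum(vapply(fit$steps, function(d)
    pcm_expected(fit$theta[["P001"]], d)$E, numeric(1)))
  expect_equal(E0, 0.3, tolerance = 1e-6)
})

test_that("unobserved categories are collapsed and reported as re-scored", {
  # category 2 never observed on item 1
  x1 <- c(0L, 0L, 1L, 1L, 3L, 3L, 4L, 4L, 0L, 1L, 3L, 4L)
  x2 <- c(0L, 1L, 2L, 3L, 4L, 0L, 1L, 2L, 3L, 4L, 2L, 1L)
  rm <- make_responses(cbind(x1, x2))
  fit <- fit_pcm(rm)
  expect_named(fit$rescored, "i01")
  expect_equal(fit$rescored[["i01"]], c(0L, 1L, 3L, 4L))
  expect_length(fit$steps[["i01"]], 3L)  # 4 observed categories -> 3 steps
  expect_length(fit$steps[["i02"]], 4L)
})

test_that("infit/outfit match a direct-summation oracle on a tiny fixture", {
  # hand-built 3 persons x 2 items with fixed theta and steps
  theta <- c(-0.5, 0.3, 1.1)
  steps <- list(i01 = c(-0.4, 0.6), i02 = c(0.2))
  X <- rbind(c(1L, 0L), c(2L, 1L), c(0L, 1L))
  dimnames(X) <- list(c("P001", "P002", "P003"), c("i01", "i02"))
  fake <- structure(list(
    item_ids = c("i01", "i02"), max_category = c(i01 = 2L, i02 = 1L),
    steps = steps, step_se = list(i01 = c(1, 1), i02 = 1),
    theta = stats::setNames(theta, rownames(X)),
    theta_se = stats::setNames(rep(1, 3), rownames(X)),
    extreme = stats::setNames(rep(FALSE, 3), rownames(X)),
    dropped_persons = character(0), converged = TRUE, iterations = 0L,
    rescored = list(), values = X), class = "pcm_fit")
  fs <- item_fit_statistics(fake)
  for (j in 1:2) {
    id <- c("i01", "i02")[j]
    E <- numeric(3); W <- numeric(3)
    for (n in 1:3) {
      p <- oracle_pcm_probs(theta[n], steps[[id]])
      cats <- 0:(length(p) - 1)
      E[n] <- sum(cats * p); W[n] <- sum((cats - E[n])^2 * p)
    }
    res2 <- (X[, j] - E)^2
    expect_equal(fs$infit_mnsq[fs$item_id == id], sum(res2) / sum(W),
                 tolerance = 1e-12)
    expect_equal(fs$outfit_mnsq[fs$item_id == id], mean(res2 / W),
                 tolerance = 1e-12)
  }
})

test_that("the misfit flag follows the configured band elementwise", {
  set.seed(27)
  inst <- make_instrument(6)
  cfg <- simulation_config(n_persons = 100, theta_mean = 0, theta_sd = 1.5,
                           instrument = inst,
                           item_steps = default_item_steps(inst), seed = 44)
  fit <- fit_pcm(simulate_pcm_responses(cfg)$responses)
  for (band in list(c(0.60, 1.40), infit_band_narrow())) {
    fs <- item_fit_statistics(fit, run_config(infit_band = band))
    expect_identical(fs$misfit,
                     fs$infit_mnsq < band[1] | fs$infit_mnsq > band[2] |
                       fs$outfit_mnsq < band[1] | fs$outfit_mnsq > band[2])
  }
})

test_that("separation and reliability satisfy R = G^2/(1+G^2) exactly", {
  expect_equal(reliability_from_separation(2), 0.8, tolerance = 1e-12)
  expect_equal(separation_from_reliability(0.5), 1, tolerance = 1e-12)
  set.seed(16)
  inst <- make_instrument(6)
  cfg <- simulation_config(n_persons = 150, theta_mean = 0, theta_sd = 1.5,
                           instrument = inst,
                           item_steps = default_item_steps(inst), seed = 33)
  fit <- fit_pcm(simulate_pcm_responses(cfg)$responses)
  sc <- separation_reliability(fit)
  expect_equal(sc$person_reliability,
               reliability_from_separation(sc$person_separation),
               tolerance = 1e-12)
  expect_equal(sc$item_reliability,
               reliability_from_separation(sc$item_separation),
               tolerance = 1e-12)
  expect_true(sc$person_reliability >= 0 && sc$person_reliability < 1)
})

test_that("theta confidence intervals attain near-nominal coverage", {
  inst <- make_instrument(12)
  cfg <- simulation_config(n_persons = 1000, theta_mean = 0, theta_sd = 1.5,
                           instrument = inst,
                           item_steps = default_item_steps(inst), seed = 5)
  d <- simulate_pcm_responses(cfg)
  fit <- fit_pcm(d$responses)
  keep <- !fit$extreme
  cover <- mean(abs(fit$theta[keep] - d$theta[keep]) <=
                  1.96 * fit$theta_se[keep])
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})
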