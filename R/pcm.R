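# Partial Credit Model machinery.
#
# For an item with step difficulties d_1..d_m, the probability that a person
# at theta responds in category x (0..m) is
#   P(x) = exp(sum_{j<=x} (theta - d_j)) / sum_{h=0}^{m} exp(sum_{j<=h} (theta - d_j))
# with the empty sum equal to 0.  Estimation is joint maximum likelihood
# (persons and item steps estimated together by alternating Newton-Raphson),
# identified by centring the grand mean of item step means at zero.

#' Partial Credit Model category probabilities
#'
#' @param theta Person location(s), logits (vector allowed).
#' @param steps Numeric vector of step difficulties `d_1..d_m` (logits).
#' @return A `length(theta) x (m+1)` matrix of category probabilities
#'   (a plain vector if `theta` is scalar); rows sum to 1.  Stable for
#'   `|theta - d|` up to several hundred logits.
#' @export
pcm_category_probs <- function(theta, steps) {
  if (any(!is.finite(steps))) stop("non-finite step difficulty")
  if (any(!is.finite(theta))) stop("non-finite theta")
  m <- length(steps)
  # cumulative logit for category h: h*theta - sum_{j<=h} d_j
  psi <- outer(theta, 0:m) - rep(c(0, cumsum(steps)), each = length(theta))
  psi <- psi - apply(psi, 1L, max)       # guard against overflow
  p <- exp(psi)
  p <- p / rowSums(p)
  if (length(theta) == 1L) drop(p) else p
}

#' Expected score and variance under the Partial Credit Model
#'
#' @inheritParams pcm_category_probs
#' @return List with `E` (expected category) and `W` (category variance),
#'   each aligned with `theta`.
#' @export
pcm_expected <- function(theta, steps) {
  p <- pcm_category_probs(theta, steps)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  cats <- seq_len(ncol(p)) - 1
  E <- drop(p %*% cats)
  E2 <- drop(p %*% cats^2)
  list(E = E, W = pmax(E2 - E^2, 0))
}

# Per-person raw score and maximum attainable score over non-missing items.
raw_and_max <- function(X, m) {
  obs <- !is.na(X)
  r <- rowSums(X, na.rm = TRUE)
  mx <- obs %*% m
  list(r = as.numeric(r), max = as.numeric(mx))
}

# Collapse categories never observed for an item into their neighbour, so
# every step stays estimable on small datasets.  Returns the recoded column,
# the new top category, and the observed->recoded mapping (NULL if intact).
collapse_unobserved <- function(x, m) {
  obs <- sort(unique(x[!is.na(x)]))
  if (length(obs) < 2L)
    stop("item has fewer than 2 observed categories; steps inestimable")
  if (identical(obs, 0:m)) return(list(x = x, m = m, map = NULL))
  list(x = match(x, obs) - 1L, m = length(obs) - 1L, map = obs)
}

#' Fit a Partial Credit Model by joint maximum likelihood
#'
#' Alternating Newton-Raphson updates of person locations and item step
#' difficulties (JMLE/"UCON"), the estimation family whose native outputs
#' are the person/item separation indices and mean-square fit statistics
#' reported for this instrument.  Persons with zero or perfect raw scores
#' carry no information about relative locations and are excluded from
#' estimation; they receive extrapolated measures at an adjusted raw score
#' 0.3 categories in from the extreme, the conventional reporting device.
#' Items with unobserved middle categories are re-scored by collapsing the
#' empty category into its neighbour (recorded in `$rescored`).
#'
#' @param responses A [response_matrix()]; ordinal items only.
#' @param cfg A [run_config()]; `jmle_tol` (maximum parameter change, in
#'   logits) and `jmle_max_iter` control convergence.
#' @param bias_correction Apply the first-order JMLE bias correction,
#'   shrinking the centred step estimates by `(L-1)/L` for `L` items
#'   (off by default; JMLE step estimates are reported raw, as the
#'   classical reporting software does).  JMLE item parameters are
#'   inflated by roughly `L/(L-1)`, so the correction matters for
#'   parameter-recovery studies with few items.
#' @return An object of class `pcm_fit`: step difficulties and standard
#'   errors per item, person measures `theta` and standard errors for every
#'   person (extremes extrapolated), `dropped_persons`, convergence state,
#'   and the (possibly re-scored) response matrix used.
#' @export
fit_pcm <- function(responses, cfg = run_config(), bias_correction = FALSE) {
  stopifnot(inherits(responses, "response_matrix"))
  X <- responses$values
  items <- responses$items
  if (ncol(X) < 2L || nrow(X) < 2L)
    stop("need at least 2 items and 2 persons")
  m <- as.integer(items$max_category)
  item_ids <- items$item_id

  rescored <- list()
  for (j in seq_along(item_ids)) {
    cc <- collapse_unobserved(X[, j], m[j])
    if (!is.null(cc$map)) {
      X[, j] <- cc$x
      m[j] <- cc$m
      rescored[[item_ids[j]]] <- cc$map
    }
  }

  rm0 <- raw_and_max(X, m)
  extreme <- rm0$r == 0 | rm0$r == rm0$max
  if (sum(!extreme) < 2L)
    stop("fewer than 2 non-extreme persons; model not estimable")
  Xe <- X[!extreme, , drop = FALSE]
  rme <- raw_and_max(Xe, m)

  theta <- log((rme$r + 0.5) / (rme$max - rme$r + 0.5))
  steps <- lapply(m, function(mi) numeric(mi))
  n_e <- nrow(Xe)

  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    max_change <- 0

    # --- person update ---
    num <- rme$r
    den <- numeric(n_e)
    for (j in seq_along(item_ids)) {
      ew <- pcm_expected(theta, steps[[j]])
      obs <- !is.na(Xe[, j])
      num[obs] <- num[obs] - ew$E[obs]
      den[obs] <- den[obs] + ew$W[obs]
    }
    dtheta <- ifelse(den > 0, num / den, 0)
    dtheta <- pmax(pmin(dtheta, 1), -1)
    theta <- theta + dtheta
    max_change <- max(max_change, abs(dtheta))

    # --- item updates (Newton on each item's step vector) ---
    for (j in seq_along(item_ids)) {
      x <- Xe[, j]
      obs <- !is.na(x)
      p <- pcm_category_probs(theta[obs], steps[[j]])
      if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
      mj <- m[j]
      # S[, k] = P(X >= k), k = 1..mj
      S <- t(apply(p, 1L, function(z) rev(cumsum(rev(z)))))[, -1, drop = FALSE]
      T_obs <- vapply(seq_len(mj), function(k) sum(x[obs] >= k), numeric(1))
      g <- colSums(S) - T_obs
      C <- matrix(0, mj, mj)
      for (k in seq_len(mj)) for (l in seq_len(mj)) {
        C[k, l] <- sum(S[, max(k, l)] - S[, k] * S[, l])
      }
      dd <- tryCatch(solve(C + diag(1e-8, mj), g),
                     error = function(e) g / (diag(C) + 1e-8))
      dd <- pmax(pmin(dd, 1), -1)
      steps[[j]] <- steps[[j]] + dd
      max_change <- max(max_change, abs(dd))
    }

    # --- identification: grand mean of item step means at zero ---
    centre <- mean(vapply(steps, mean, numeric(1)))
    steps <- lapply(steps, function(d) d - centre)
    theta <- theta - centre

    if (max_change < cfg$jmle_tol) { converged <- TRUE; break }
    if (iter >= cfg$jmle_max_iter) break
  }

  if (bias_correction) {
    L <- length(item_ids)
    steps <- lapply(steps, function(d) d * (L - 1) / L)
  }

  # standard errors at the solution
  theta_se <- {
    den <- numeric(n_e)
    for (j in seq_along(item_ids)) {
      ew <- pcm_expected(theta, steps[[j]])
      obs <- !is.na(Xe[, j])
      den[obs] <- den[obs] + ew$W[obs]
    }
    1 / sqrt(pmax(den, .Machine$double.eps))
  }
  step_se <- lapply(seq_along(item_ids), function(j) {
    x <- Xe[, j]; obs <- !is.na(x)
    p <- pcm_category_probs(theta[obs], steps[[j]])
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    mj <- m[j]
    S <- t(apply(p, 1L, function(z) rev(cumsum(rev(z)))))[, -1, drop = FALSE]
    C <- matrix(0, mj, mj)
    for (k in seq_len(mj)) for (l in seq_len(mj))
      C[k, l] <- sum(S[, max(k, l)] - S[, k] * S[, l])
    sqrt(diag(solve(C + diag(1e-8, mj))))
  })
  names(steps) <- names(step_se) <- item_ids

  # extrapolated measures for extreme-score persons: solve expected score
  # = 0.3 (zero score) or max - 0.3 (perfect score) under the final steps
  all_theta <- numeric(nrow(X)); all_se <- numeric(nrow(X))
  all_theta[!extreme] <- theta; all_se[!extreme] <- theta_se
  if (any(extreme)) {
    for (i in which(extreme)) {
      obs_j <- which(!is.na(X[i, ]))
      r_adj <- if (rm0$r[i] == 0) 0.3 else rm0$max[i] - 0.3
      f <- function(th) {
        sum(vapply(obs_j, function(j) pcm_expected(th, steps[[j]])$E,
                   numeric(1))) - r_adj
      }
      th <- stats::uniroot(f, c(-30, 30), tol = 1e-8, extendInt = "upX")$root
      info <- sum(vapply(obs_j, function(j) pcm_expected(th, steps[[j]])$W,
                         numeric(1)))
      all_theta[i] <- th
      all_se[i] <- 1 / sqrt(max(info, .Machine$double.eps))
    }
  }
  names(all_theta) <- names(all_se) <- rownames(X)

  structure(list(
    item_ids = item_ids, max_category = stats::setNames(m, item_ids),
    steps = steps, step_se = step_se,
    theta = all_theta, theta_se = all_se,
    extreme = stats::setNames(extreme, rownames(X)),
    dropped_persons = rownames(X)[extreme],
    converged = converged, iterations = iter,
    rescored = rescored, values = X), class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat("Partial Credit Model fit (JMLE):", length(x$item_ids), "items,",
      length(x$theta), "persons (", length(x$dropped_persons),
      "extreme )\n")
  cat(if (x$converged) "Converged" else "NOT converged", "after",
      x$iterations, "iterations\n")
  if (length(x$rescored))
    cat("Re-scored items (collapsed unobserved categories):",
        paste(names(x$rescored), collapse = ", "), "\n")
  invisible(x)
}

#' Infit and outfit mean-square item fit statistics
#'
#' Standardised residual `z^2 = (x - E)^2 / W` per response; outfit is its
#' unweighted mean over persons, infit the information-weighted version
#' `sum (x - E)^2 / sum W`.  Both have expectation near 1 under model fit;
#' an item is flagged as misfitting when either statistic leaves the
#' configured band.  Extreme-score persons (dropped from estimation) are
#' excluded, as are responses with vanishing model variance.
#'
#' @param fit A [fit_pcm()] result.
#' @param cfg A [run_config()]; `infit_band` gives the acceptance band
#'   (default 0.60--1.40).
#' @return Data frame of class `item_fit_stats` with columns `item_id`,
#'   `infit_mnsq`, `outfit_mnsq`, `misfit`, `n_used`.
#' @export
item_fit_statistics <- function(fit, cfg = run_config()) {
  stopifnot(inherits(fit, "pcm_fit"))
  keep <- !fit$extreme
  X <- fit$values[keep, , drop = FALSE]
  theta <- fit$theta[keep]
  out <- lapply(seq_along(fit$item_ids), function(j) {
    x <- X[, j]
    obs <- which(!is.na(x))
    ew <- pcm_expected(theta[obs], fit$steps[[j]])
    usable <- ew$W > 1e-10
    if (!any(usable))
      return(data.frame(item_id = fit$item_ids[j], infit_mnsq = NA_real_,
                        outfit_mnsq = NA_real_, misfit = NA, n_used = 0L))
    res2 <- (x[obs][usable] - ew$E[usable])^2
    infit <- sum(res2) / sum(ew$W[usable])
    outfit <- mean(res2 / ew$W[usable])
    data.frame(item_id = fit$item_ids[j], infit_mnsq = infit,
               outfit_mnsq = outfit,
               misfit = infit < cfg$infit_band[1] | infit > cfg$infit_band[2] |
                 outfit < cfg$infit_band[1] | outfit > cfg$infit_band[2],
               n_used = sum(usable))
  })
  out <- do.call(rbind, out)
  class(out) <- c("item_fit_stats", "data.frame")
  out
}

#' Separation and reliability indices
#'
#' For persons: the observed variance of the estimated measures is split
#' into true spread and error, `SD_adj^2 = max(0, var(theta) - mean(se^2))`;
#' reliability `R = SD_adj^2 / var(theta)` and separation
#' `G = sqrt(R / (1 - R))`, so `R = G^2 / (1 + G^2)`.  Items are treated
#' analogously over the pooled step-difficulty estimates.  Extreme persons
#' (extrapolated measures) are excluded.
#'
#' @param fit A [fit_pcm()] result.
#' @return List of class `scale_stats`: `person_separation`,
#'   `person_reliability`, `item_separation`, `item_reliability`.
#' @export
separation_reliability <- function(fit) {
  stopifnot(inherits(fit, "pcm_fit"))
  sep_rel <- function(est, se) {
    v <- stats::var(est)
    if (!is.finite(v) || v <= 0) return(c(G = 0, R = 0))
    adj <- max(0, v - mean(se^2))
    R <- adj / v
    G <- if (R >= 1) Inf else sqrt(R / (1 - R))
    c(G = G, R = R)
  }
  pers <- sep_rel(fit$theta[!fit$extreme], fit$theta_se[!fit$extreme])
  itm <- sep_rel(unlist(fit$steps), unlist(fit$step_se))
  structure(list(person_separation = unname(pers["G"]),
                 person_reliability = unname(pers["R"]),
                 item_separation = unname(itm["G"]),
                 item_reliability = unname(itm["R"])),
            class = "scale_stats")
}

#' Reliability implied by a separation index (and vice versa)
#'
#' The separation index `G` and separation reliability `R` are linked by
#' `R = G^2 / (1 + G^2)`, equivalently `G = sqrt(R / (1 - R))`.
#'
#' @param G Separation index (non-negative).
#' @return Reliability in `[0, 1)`.
#' @export
reliability_from_separation <- function(G) {
  stopifnot(all(G >= 0))
  G^2 / (1 + G^2)
}

#' @rdname reliability_from_separation
#' @param R Reliability in `[0, 1)`.
#' @export
separation_from_reliability <- function(R) {
  stopifnot(all(R >= 0), all(R < 1))
  sqrt(R / (1 - R))
}
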