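# Synthetic-data generator emulating the multi-centre observational study
# design: 151 MS patients recruited by 28 clinicians (23 returning the pivot
# survey), ordinal responses generated from a Partial Credit Model, and
# referral recommendations linked to the completed questionnaire's raw
# total score.  One run seed; each stage derives its own sub-stream by
# name, so adding a stage never shifts another stage's draws.

#' Default generating step difficulties for an instrument
#'
#' Item locations are spread evenly over `location_range` and each ordinal
#' item's four steps sit at location + (-1.5, -0.5, 0.5, 1.5) logits;
#' dichotomous items get a single step at their location.
#'
#' @param instrument An [instrument()].
#' @param location_range Range of item locations (logits).
#' @return Named list of step-difficulty vectors, one per item.
#' @export
default_item_steps <- function(instrument = absst_instrument(),
                               location_range = c(-1, 1)) {
  n <- nrow(instrument)
  loc <- seq(location_range[1], location_range[2], length.out = n)
  out <- lapply(seq_len(n), function(i) {
    m <- instrument$max_category[i]
    if (m == 1L) loc[i]
    else loc[i] + seq(-1.5, 1.5, length.out = m)
  })
  names(out) <- instrument$item_id
  out
}

#' Study-like generating step difficulties
#'
#' Item locations laid out by subscale, reflecting the endorsement pattern
#' typical of bladder-symptom instruments in a predominantly mildly
#' affected MS population: symptom frequency/intensity items are the most
#' endorsed (lowest locations), coping items intermediate, impact items the
#' least endorsed (highest locations).  Steps sit at location
#' + (-1.5 ... 1.5) as in [default_item_steps()].
#'
#' @param instrument An [instrument()].
#' @return Named list of step-difficulty vectors.
#' @export
study_item_steps <- function(instrument = absst_instrument()) {
  bands <- list(symptom_frequency = c(-2.2, -1.6),
                symptom_intensity = c(-2.0, -1.2),
                coping = c(-1.0, 0.2),
                impact = c(0.5, 2.0),
                help_seeking = c(-0.5, -0.5))
  loc <- numeric(nrow(instrument))
  for (s in names(bands)) {
    idx <- which(instrument$subscale == s)
    if (length(idx))
      loc[idx] <- seq(bands[[s]][1], bands[[s]][2],
                      length.out = max(length(idx), 2L))[seq_along(idx)]
  }
  out <- lapply(seq_len(nrow(instrument)), function(i) {
    m <- instrument$max_category[i]
    if (m == 1L) loc[i]
    else loc[i] + seq(-1.5, 1.5, length.out = m)
  })
  names(out) <- instrument$item_id
  out
}

#' Simulation configuration
#'
#' Defaults mirror the study that motivated the instrument: 151 patients,
#' 28 recruiting clinicians of whom 23 return the pivot survey, a 0--4
#' Partial Credit response process over 16 ordinal items plus a yes/no
#' item, and referral recommendations drawn from a logistic model on the
#' raw total score of the completed questionnaire.
#'
#' @param n_persons Number of patients.
#' @param theta_mean,theta_sd Latent severity distribution (logits).
#' @param instrument An [instrument()].
#' @param item_steps Named list of generating step difficulties; default
#'   [default_item_steps()].
#' @param referral_intercept,referral_slope Logistic-link coefficients of
#'   referral on the raw total score.
#' @param clinician_count Number of recruiting clinicians.
#' @param clinician_response_rate Probability a clinician returns the
#'   survey.
#' @param relevance_prob Per-item probability a responding clinician marks
#'   the item relevant; `NULL` means "use the true rule's endorsement
#'   percentages".
#' @param jitter_prob Probability a reported threshold is off by one
#'   category (clipped to range).
#' @param seed Integer master seed.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_persons = 151L, theta_mean = -3,
                              theta_sd = 2,
                              instrument = absst_instrument(),
                              item_steps = study_item_steps(instrument),
                              referral_intercept = -4, referral_slope = 0.3,
                              clinician_count = 28L,
                              clinician_response_rate = 23 / 28,
                              relevance_prob = NULL, jitter_prob = 0.1,
                              seed = 20130709L) {
  stopifnot(n_persons >= 2L, theta_sd > 0, clinician_count >= 1L,
            clinician_response_rate > 0, clinician_response_rate <= 1,
            jitter_prob >= 0, jitter_prob <= 1)
  if (!setequal(names(item_steps), instrument$item_id))
    stop("item_steps must be named by the instrument's item_ids")
  m <- instrument$max_category
  for (i in seq_len(nrow(instrument))) {
    d <- item_steps[[instrument$item_id[i]]]
    if (length(d) != m[i])
      stop("item '", instrument$item_id[i], "' needs ", m[i], " steps")
    if (any(!is.finite(d)))
      stop("non-finite step difficulty for item '",
           instrument$item_id[i], "'")
  }
  structure(list(n_persons = as.integer(n_persons),
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 instrument = instrument, item_steps = item_steps,
                 referral_intercept = referral_intercept,
                 referral_slope = referral_slope,
                 clinician_count = as.integer(clinician_count),
                 clinician_response_rate = clinician_response_rate,
                 relevance_prob = relevance_prob,
                 jitter_prob = jitter_prob, seed = as.integer(seed)),
            class = "sim_config")
}

# sample one response per person for one item from PCM category probabilities
sample_pcm_item <- function(theta, steps) {
  p <- pcm_category_probs(theta, steps)
  if (is.null(dim(p))) p <- matrix(p, nrow = length(theta), byrow = TRUE)
  cp <- t(apply(p, 1L, cumsum))
  u <- stats::runif(length(theta))
  as.integer(rowSums(cp < u))
}

#' Simulate Partial Credit Model responses
#'
#' Draws each person's latent severity from `N(theta_mean, theta_sd^2)` and
#' every response from the Partial Credit category probabilities at that
#' severity.  Bit-reproducible under the configuration seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `responses` (a [response_matrix()]) and `theta`
#'   (true per-person severities).
#' @export
simulate_pcm_responses <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "responses"))
  theta <- stats::rnorm(cfg$n_persons, cfg$theta_mean, cfg$theta_sd)
  inst <- cfg$instrument
  X <- matrix(NA_integer_, cfg$n_persons, nrow(inst),
              dimnames = list(sprintf("P%03d", seq_len(cfg$n_persons)),
                              inst$item_id))
  for (j in seq_len(nrow(inst)))
    X[, j] <- sample_pcm_item(theta, cfg$item_steps[[inst$item_id[j]]])
  list(responses = response_matrix(X, inst),
       theta = stats::setNames(theta, rownames(X)))
}

#' Simulate a clinician pivot survey
#'
#' Clinicians respond with probability `clinician_response_rate`; each
#' responder marks each item relevant with the item's relevance probability
#' (by default the true rule's endorsement percentage) and, when relevant,
#' reports the true threshold, jittered by one category with probability
#' `jitter_prob` and clipped to the item's range.
#'
#' @param cfg A [simulation_config()].
#' @param true_rule A [pivot_rule()] giving each item's true threshold (and
#'   default endorsement probabilities).
#' @return A [clinician_survey()] over the responding clinicians.
#' @export
simulate_clinician_survey <- function(cfg, true_rule) {
  stopifnot(inherits(cfg, "sim_config"))
  inst <- cfg$instrument
  thr_true <- true_rule$flag_threshold[match(inst$item_id,
                                             true_rule$item_id)]
  if (anyNA(thr_true))
    stop("true_rule must cover every instrument item")
  if (any(thr_true < 1L | thr_true > inst$max_category))
    stop("true thresholds outside category ranges")
  rel_p <- cfg$relevance_prob
  if (is.null(rel_p))
    rel_p <- true_rule$endorsement_pct[match(inst$item_id,
                                             true_rule$item_id)] / 100
  rel_p <- rep_len(rel_p, nrow(inst))
  set.seed(stage_seed(cfg$seed, "clinician_survey"))
  responders <- which(stats::runif(cfg$clinician_count) <
                        cfg$clinician_response_rate)
  if (!length(responders)) responders <- 1L
  n_r <- length(responders)
  relevant <- matrix(FALSE, n_r, nrow(inst))
  threshold <- matrix(NA_integer_, n_r, nrow(inst))
  for (j in seq_len(nrow(inst))) {
    relevant[, j] <- stats::runif(n_r) < rel_p[j]
    jit <- ifelse(stats::runif(n_r) < cfg$jitter_prob,
                  sample(c(-1L, 1L), n_r, replace = TRUE), 0L)
    t_j <- pmin(pmax(thr_true[j] + jit, 1L), inst$max_category[j])
    threshold[relevant[, j], j] <- t_j[relevant[, j]]
  }
  clinician_survey(relevant, threshold, inst,
                   clinicians = sprintf("C%02d", responders))
}

#' Simulate referral recommendations
#'
#' `referred ~ Bernoulli(plogis(a + b * score))` on the supplied raw total
#' scores, emulating clinicians judging the completed questionnaire.
#'
#' @param scores Per-person raw total scores (named).
#' @param cfg A [simulation_config()] supplying `referral_intercept` (a),
#'   `referral_slope` (b) and the seed.
#' @return A [referral_labels()] data frame aligned with `scores`.
#' @export
simulate_referrals <- function(scores, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "referrals"))
  p <- stats::plogis(cfg$referral_intercept + cfg$referral_slope * scores)
  referral_labels(stats::runif(length(scores)) < p,
                  persons = names(scores))
}

#' Deterministic score/label fixture for the published cut-point table
#'
#' Returns the unique allocation of 151 patients (49 referred, 102 not)
#' to raw-score bins bounded by the published cut-points (21, 9, 6, 4, 1)
#' that reproduces every printed sensitivity and specificity:
#' referred group 1 x 21, 33 x 9, 8 x 6, 4 x 4, 2 x 1, 1 x 0;
#' non-referred group 4 x 9, 3 x 6, 25 x 4, 55 x 1, 15 x 0.
#' Scores sit at bin lower edges; any placement within a bin yields the
#' same cut-point table.  Only the binned counts are constrained, so the
#' fixture reproduces the per-cut table but not the overall
#' continuous-score c-statistic.
#'
#' @return List with `scores` (named integer vector, length 151) and
#'   `labels` (a [referral_labels()]).
#' @export
table3_fixture <- function() {
  ref_scores <- rep(c(21L, 9L, 6L, 4L, 1L, 0L), c(1L, 33L, 8L, 4L, 2L, 1L))
  non_scores <- rep(c(9L, 6L, 4L, 1L, 0L), c(4L, 3L, 25L, 55L, 15L))
  scores <- c(ref_scores, non_scores)
  referred <- rep(c(TRUE, FALSE), c(length(ref_scores), length(non_scores)))
  persons <- sprintf("P%03d", seq_along(scores))
  list(scores = stats::setNames(scores, persons),
       labels = referral_labels(referred, persons = persons))
}
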