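#' Default trial timing for the luggage-screening task
#'
#' Phase durations (seconds) of one trial of the X-ray luggage-screening
#' advice-taking task: fixation cross, advice cue, bag image, decision window,
#' a jittered fixation, feedback, and a second jittered fixation. Jitters are
#' drawn between `jitter_min` and `jitter_max` with mean `jitter_mean`.
#'
#' @param fixation,advice,bag,decision,feedback fixed phase durations in s.
#' @param jitter_min,jitter_max,jitter_mean jitter constraints in s.
#' @return a list of timing constants, class `"task_timing"`.
#' @export
task_timing <- function(fixation = 0.5, advice = 2, bag = 4, decision = 4,
                        feedback = 2,
                        jitter_min = 1, jitter_max = 7, jitter_mean = 4) {
  stopifnot(fixation > 0, advice > 0, bag > 0, decision > 0, feedback > 0,
            jitter_min <= jitter_mean, jitter_mean <= jitter_max)
  structure(list(fixation = fixation, advice = advice, bag = bag,
                 decision = decision, feedback = feedback,
                 jitter_min = jitter_min, jitter_max = jitter_max,
                 jitter_mean = jitter_mean),
            class = "task_timing")
}

# truncated-normal draw on [lo, hi] by inverse-CDF sampling
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a stimulus manifest
#'
#' Builds a table of X-ray luggage images with target-present flags and
#' normative ratings (clutter, difficulty, confidence in finding the target)
#' on 7-point scales, drawn from truncated normal distributions.
#'
#' @param n_target,n_nontarget number of target-present / target-absent images.
#' @param seed optional RNG seed.
#' @param rating_means,rating_sds named numeric vectors (clutter, difficulty,
#'   confidence) giving the rating distributions before truncation to `[1, 7]`.
#' @return a data.frame with columns `image_id`, `target_present`,
#'   `clutter_rating`, `difficulty_rating`, `confidence_rating`.
#' @export
make_stimulus_manifest <- function(n_target, n_nontarget, seed = NULL,
                                   rating_means = c(clutter = 4.1,
                                                    difficulty = 3.5,
                                                    confidence = 3.2),
                                   rating_sds = c(clutter = 0.3,
                                                  difficulty = 0.4,
                                                  confidence = 0.6)) {
  if (n_target < 0 || n_nontarget < 0)
    stop("counts must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- n_target + n_nontarget
  out <- data.frame(
    image_id = if (n > 0) sprintf("img%03d", seq_len(n)) else character(0),
    target_present = rep(c(TRUE, FALSE), c(n_target, n_nontarget)),
    clutter_rating = rtruncnorm(n, rating_means[["clutter"]],
                                rating_sds[["clutter"]], 1, 7),
    difficulty_rating = rtruncnorm(n, rating_means[["difficulty"]],
                                   rating_sds[["difficulty"]], 1, 7),
    confidence_rating = rtruncnorm(n, rating_means[["confidence"]],
                                   rating_sds[["confidence"]], 1, 7),
    stringsAsFactors = FALSE
  )
  out
}

#' Largest-remainder integer allocation
#'
#' Allocates `n` items to categories in proportion to `props`, rounding by the
#' largest-remainder (Hamilton) rule so the counts sum exactly to `n` and total
#' absolute deviation from `n * props` is minimal.
#'
#' @param n total count.
#' @param props numeric proportions, must sum to 1.
#' @return integer vector of counts, same names as `props`.
#' @export
largest_remainder <- function(n, props) {
  if (abs(sum(props) - 1) > 1e-8) stop("proportions must sum to 1")
  if (any(props < 0)) stop("proportions must be non-negative")
  exact <- n * props
  base <- floor(exact)
  rem <- exact - base
  k <- n - sum(base)
  if (k > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(k)]
    base[give] <- base[give] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Generate jittered fixation durations
#'
#' Draws `n` durations from a truncated exponential-like law on
#' `[min_s, max_s]` and applies an iterative mean-preserving correction so the
#' sample mean matches `mean_s` (to ~1e-6 s) while every draw stays within the
#' bounds. With `n = 1` the single duration is the mean.
#'
#' @param n number of durations.
#' @param min_s,max_s,mean_s bounds and target mean, seconds.
#' @param seed optional RNG seed.
#' @return numeric vector of durations.
#' @export
generate_jitter <- function(n, min_s = 1, max_s = 7, mean_s = 4, seed = NULL) {
  if (min_s > mean_s || mean_s > max_s)
    stop("infeasible jitter constraints: need min_s <= mean_s <= max_s")
  if (n == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  if (n == 1) return(mean_s)
  span <- max_s - min_s
  # signed-rate truncated exponential: rate 0 reduces to uniform; sign tilts
  # the density toward whichever end brings the mean to target
  trunc_exp_mean <- function(r) {
    if (abs(r) < 1e-9) return(span / 2)
    1 / r - span * exp(-r * span) / (1 - exp(-r * span))
  }
  target <- mean_s - min_s
  r <- tryCatch(
    stats::uniroot(function(r) trunc_exp_mean(r) - target,
                   c(-50, 50), tol = 1e-10)$root,
    error = function(e) 0)
  u <- stats::runif(n)
  if (abs(r) < 1e-9) {
    x <- min_s + span * u
  } else {
    x <- min_s - log(1 - u * (1 - exp(-r * span))) / r
  }
  # iterative mean correction: shift, clamp, repeat
  for (i in 1:200) {
    d <- mean_s - mean(x)
    if (abs(d) < 1e-8) break
    x <- pmin(pmax(x + d, min_s), max_s)
  }
  x
}

#' Generate a randomized trial schedule
#'
#' Lays out a session of the advice-taking task: the advice-type composition is
#' realized by largest-remainder rounding over the whole session, trials are
#' dealt to runs as evenly as possible per type, the order within each run is
#' randomized, and per-trial phase onsets follow the fixed phase durations plus
#' generated jitters (mean-corrected per run).
#'
#' Advice types map to advice labels: hits and correct rejections are good
#' (advice-congruent) advice; false alarms are bad (advice-incongruent).
#'
#' @param n_trials total number of trials in the session.
#' @param composition named proportions over
#'   `c("hit", "correct_rejection", "false_alarm")`; must sum to 1.
#' @param runs number of runs; `n_trials` must be divisible by `runs`.
#' @param timing a [task_timing()] object.
#' @param agent `"human"` or `"machine"` (recorded per trial).
#' @param seed optional RNG seed.
#' @return a data.frame of class `"event_schedule"`, one row per trial, with
#'   `trial_index`, `run`, `advice_type`, `advice_label`, `agent`, and
#'   `onset_<phase>` / `dur_<phase>` columns for phases fixation, advice, bag,
#'   decision, jitter1, feedback, jitter2 (onsets in seconds from run start).
#' @export
generate_trial_schedule <- function(n_trials = 64,
                                    composition = c(hit = 0.5,
                                                    correct_rejection = 0.1,
                                                    false_alarm = 0.4),
                                    runs = 2,
                                    timing = task_timing(),
                                    agent = c("human", "machine"),
                                    seed = NULL) {
  agent <- match.arg(agent)
  if (abs(sum(composition) - 1) > 1e-8)
    stop("composition proportions must sum to 1")
  if (n_trials %% runs != 0)
    stop("n_trials must be divisible by runs")
  if (!is.null(seed)) set.seed(seed)
  types <- c("hit", "correct_rejection", "false_alarm")
  composition <- composition[types]
  counts <- largest_remainder(n_trials, composition)

  # deal each type's count to runs as evenly as possible
  per_run <- matrix(0L, nrow = length(types), ncol = runs,
                    dimnames = list(types, NULL))
  for (ty in types) {
    base <- counts[[ty]] %/% runs
    extra <- counts[[ty]] %% runs
    per_run[ty, ] <- base + as.integer(seq_len(runs) <= extra)
  }
  # the even deal can leave runs unequal in size; rebalance by moving trials
  # of the most abundant type from over-full to under-full runs
  n_per_run <- n_trials %/% runs
  repeat {
    sizes <- colSums(per_run)
    over <- which(sizes > n_per_run)[1]
    under <- which(sizes < n_per_run)[1]
    if (is.na(over) || is.na(under)) break
    ty <- which.max(per_run[, over])
    per_run[ty, over] <- per_run[ty, over] - 1L
    per_run[ty, under] <- per_run[ty, under] + 1L
  }

  phase_names <- c("fixation", "advice", "bag", "decision", "jitter1",
                   "feedback", "jitter2")
  rows <- vector("list", runs)
  trial0 <- 0L
  for (r in seq_len(runs)) {
    type_vec <- sample(rep(types, per_run[, r]))
    n_r <- length(type_vec)
    jit <- generate_jitter(2 * n_r, timing$jitter_min, timing$jitter_max,
                           timing$jitter_mean)
    dur <- cbind(fixation = rep(timing$fixation, n_r),
                 advice = rep(timing$advice, n_r),
                 bag = rep(timing$bag, n_r),
                 decision = rep(timing$decision, n_r),
                 jitter1 = jit[seq_len(n_r)],
                 feedback = rep(timing$feedback, n_r),
                 jitter2 = jit[n_r + seq_len(n_r)])
    trial_len <- rowSums(dur)
    trial_start <- cumsum(c(0, trial_len[-n_r]))
    onset <- trial_start + t(apply(cbind(0, dur[, -7, drop = FALSE]), 1,
                                   cumsum))[, seq_len(7), drop = FALSE]
    colnames(onset) <- phase_names
    df <- data.frame(trial_index = trial0 + seq_len(n_r), run = r,
                     advice_type = type_vec,
                     advice_label = ifelse(type_vec == "false_alarm",
                                           "bad", "good"),
                     agent = agent, stringsAsFactors = FALSE)
    for (ph in phase_names) {
      df[[paste0("onset_", ph)]] <- onset[, ph]
      df[[paste0("dur_", ph)]] <- dur[, ph]
    }
    rows[[r]] <- df
    trial0 <- trial0 + n_r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("event_schedule", "data.frame")
  attr(out, "timing") <- timing
  out
}

#' Duration of each run of a schedule
#' @param schedule an `event_schedule`.
#' @return numeric vector, seconds per run.
#' @export
run_duration <- function(schedule) {
  vapply(split(schedule, schedule$run),
         function(d) max(d$onset_jitter2 + d$dur_jitter2), numeric(1))
}

#' Write / read an event schedule as a long-format TSV
#'
#' One row per trial phase with columns `onset`, `duration`, `phase`,
#' `trial_index`, `run`, `advice_type`, `advice_label`, `agent`.
#'
#' @param schedule an `event_schedule`.
#' @param path file path.
#' @export
write_event_schedule <- function(schedule, path) {
  phases <- c("fixation", "advice", "bag", "decision", "jitter1",
              "feedback", "jitter2")
  long <- do.call(rbind, lapply(phases, function(ph) {
    data.frame(onset = schedule[[paste0("onset_", ph)]],
               duration = schedule[[paste0("dur_", ph)]],
               phase = ph,
               trial_index = schedule$trial_index,
               run = schedule$run,
               advice_type = schedule$advice_type,
               advice_label = schedule$advice_label,
               agent = schedule$agent,
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$run, long$onset), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_schedule
#' @export
read_event_schedule <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  wide <- unique(long[, c("trial_index", "run", "advice_type",
                          "advice_label", "agent")])
  wide <- wide[order(wide$trial_index), ]
  for (ph in unique(long$phase)) {
    sub <- long[long$phase == ph, ]
    sub <- sub[match(wide$trial_index, sub$trial_index), ]
    wide[[paste0("onset_", ph)]] <- sub$onset
    wide[[paste0("dur_", ph)]] <- sub$duration
  }
  rownames(wide) <- NULL
  class(wide) <- c("event_schedule", "data.frame")
  wide
}

#' Default behavioural agent parameters
#'
#' A single-parameter disconfirmation model: acceptance probability starts at
#' `initial_accept_prob` and is multiplied by `1 - disconfirmation_sensitivity`
#' after every error feedback. Participants paired with a human advisor are
#' modelled as more sensitive to disconfirming evidence (errors weigh more
#' heavily against a human expert's presumed credibility) than those paired
#' with a machine advisor.
#'
#' @param agent `"human"` or `"machine"`.
#' @return list with `initial_accept_prob`, `disconfirmation_sensitivity`,
#'   `agent`, `rt_meanlog`, `rt_sdlog`.
#' @export
agent_params <- function(agent = c("human", "machine")) {
  agent <- match.arg(agent)
  list(initial_accept_prob = 0.95,
       disconfirmation_sensitivity = if (agent == "human") 0.08 else 0.03,
       agent = agent,
       rt_meanlog = log(1.4), rt_sdlog = 0.3)
}

# decision matrix: accepting good advice (hit or correct rejection) is the
# normatively correct response; accepting a false alarm (searching a clean
# bag) is an error, rejecting one is correct
decision_correct <- function(advice_label, decision) {
  (advice_label == "good") == (decision == "accept")
}

#' Simulate accept/reject behaviour on a trial schedule
#'
#' Draws per-trial accept decisions from a probability that starts at
#' `params$initial_accept_prob` and decays multiplicatively by
#' `params$disconfirmation_sensitivity` after each error feedback. Correctness
#' and monetary deductions follow the task's decision matrix.
#'
#' @param schedule an `event_schedule`.
#' @param params list as returned by [agent_params()].
#' @param deduction_per_error dollars deducted per incorrect answer.
#' @param seed optional RNG seed.
#' @return data.frame of trial records with columns `trial_index`, `run`,
#'   `advice_type`, `advice_label`, `agent`, `decision`, `correct`,
#'   `response_time`, `deduction`.
#' @export
simulate_agent_responses <- function(schedule, params = agent_params(),
                                     deduction_per_error = 0.30,
                                     seed = NULL) {
  p0 <- params$initial_accept_prob
  s <- params$disconfirmation_sensitivity
  if (p0 < 0 || p0 > 1 || s < 0 || s > 1)
    stop("probabilities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(schedule)
  decision <- character(n)
  correct <- logical(n)
  p <- p0
  for (i in seq_len(n)) {
    acc <- stats::runif(1) < p
    decision[i] <- if (acc) "accept" else "reject"
    correct[i] <- decision_correct(schedule$advice_label[i], decision[i])
    if (!correct[i]) p <- max(0, min(1, p * (1 - s)))
  }
  data.frame(trial_index = schedule$trial_index, run = schedule$run,
             advice_type = schedule$advice_type,
             advice_label = schedule$advice_label,
             agent = schedule$agent,
             decision = decision, correct = correct,
             response_time = stats::rlnorm(n, params$rt_meanlog,
                                           params$rt_sdlog),
             deduction = ifelse(correct, 0, deduction_per_error),
             stringsAsFactors = FALSE)
}

#' Write / read trial records as TSV
#' @param records trial-record data.frame.
#' @param path file path.
#' @export
write_trial_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_records
#' @export
read_trial_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
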