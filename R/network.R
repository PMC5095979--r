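#' Ground-truth directed network for simulation
#'
#' Holds one VAR(1) coefficient matrix per condition. Entry `A[i, j]` is the
#' signed influence of ROI `j` at lag 1 on ROI `i` (direction `j -> i`). Every
#' condition matrix must be stable (spectral radius < 1).
#'
#' @param A named list of square coefficient matrices, one per condition.
#' @param labels ROI names (defaults to `R1..Rn`).
#' @param innovation_sd per-ROI innovation standard deviation (recycled).
#' @return object of class `"ground_truth_network"`.
#' @export
ground_truth_network <- function(A, labels = NULL, innovation_sd = 1) {
  stopifnot(is.list(A), length(A) >= 1, !is.null(names(A)))
  n <- nrow(A[[1]])
  for (cond in names(A)) {
    m <- A[[cond]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop("all condition matrices must be square with matching dimension")
    if (any(!is.finite(m)))
      stop("coefficient matrices must be finite")
    rho <- max(Mod(eigen(m, only.values = TRUE)$values))
    if (rho >= 1)
      stop(sprintf("unstable network for condition '%s': spectral radius %.3f",
                   cond, rho))
  }
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  stopifnot(length(labels) == n)
  structure(list(A = A, labels = labels, n_rois = n,
                 innovation_sd = rep_len(innovation_sd, n)),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("Ground-truth VAR(1) network: %d ROIs, conditions: %s\n",
              x$n_rois, paste(names(x$A), collapse = ", ")))
  for (cond in names(x$A)) {
    rho <- max(Mod(eigen(x$A[[cond]], only.values = TRUE)$values))
    cat(sprintf("  %s: %d nonzero edges, spectral radius %.3f\n", cond,
                sum(x$A[[cond]] != 0) - sum(diag(x$A[[cond]]) != 0), rho))
  }
  invisible(x)
}

#' Hub-and-spoke coefficient matrix
#'
#' Builds an `n_rois` x `n_rois` VAR(1) matrix in which the `hubs` nodes send
#' directed edges of weight `hub_weight` to every other node (including each
#' other, making the hub pair reciprocal) and every node has self-decay
#' `self`. This is the two-driver topology used for end-to-end recovery
#' studies: two reciprocally connected source nodes projecting to all targets.
#'
#' @param n_rois number of nodes.
#' @param hubs indices of driver nodes.
#' @param hub_weight weight of each hub out-edge.
#' @param self diagonal self-coefficient.
#' @return coefficient matrix (`A[i, j]` = influence `j -> i`).
#' @export
hub_network_matrix <- function(n_rois = 6, hubs = c(1, 2), hub_weight = 0.4,
                               self = 0.3) {
  A <- diag(self, n_rois)
  for (h in hubs) {
    A[-h, h] <- hub_weight
  }
  A
}

#' Ground-truth networks for a two-group advice study
#'
#' One network per agent group, with conditions `good`, `bad`, and `rest`.
#' The agent context persists over the whole run, so the group difference in
#' hub out-edge strength is a run-long network property: each group's hub
#' weight applies in every condition, with a mild task modulation on top
#' (task conditions use the group weight, rest a fraction of it). Conditions
#' thus differ within group and the hub out-edges differ between groups —
#' the structure the run-1 bad-advice comparison is designed to detect.
#'
#' @param n_rois,hubs,self as in [hub_network_matrix()].
#' @param hub_weight named vector `c(human = ..., machine = ...)` of hub
#'   out-edge weights during task conditions.
#' @param rest_factor multiplier on `hub_weight` during inter-trial rest.
#' @param labels ROI names.
#' @param innovation_sd innovation SD.
#' @return named list of two `ground_truth_network`s (`human`, `machine`).
#' @export
advice_study_networks <- function(n_rois = 6, hubs = c(1, 2), self = 0.3,
                                  hub_weight = c(human = 0.5, machine = 0.3),
                                  rest_factor = 0.9,
                                  labels = c("PI", "LaPreC", "RaPreC", "PCC",
                                             "rlPFC", "pTPJ"),
                                  innovation_sd = 1) {
  lapply(c(human = "human", machine = "machine"), function(g) {
    w <- hub_weight[[g]]
    task <- hub_network_matrix(n_rois, hubs, w, self)
    rest <- hub_network_matrix(n_rois, hubs, rest_factor * w, self)
    ground_truth_network(list(good = task, bad = task, rest = rest),
                         labels = labels, innovation_sd = innovation_sd)
  })
}

#' Stationary covariance of a stable VAR(1) process
#'
#' Solves the discrete Lyapunov equation `P = A P A' + Sigma` by
#' vectorization.
#'
#' @param A coefficient matrix (spectral radius < 1).
#' @param Sigma innovation covariance (defaults to identity).
#' @return stationary covariance matrix.
#' @export
var_stationary_cov <- function(A, Sigma = diag(nrow(A))) {
  n <- nrow(A)
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1)
    stop("A must be stable")
  vecP <- solve(diag(n * n) - kronecker(A, A), as.vector(Sigma))
  matrix(vecP, n, n)
}

#' Condition label of each fMRI volume
#'
#' Labels volume `k` (sampled at time `(k - 1) * TR` from run start) with the
#' advice label of the trial whose `phase` interval covers that time, and
#' `"rest"` otherwise. Stored explicitly so downstream code never re-derives
#' timing.
#'
#' @param schedule an `event_schedule`.
#' @param run which run to label.
#' @param TR repetition time, s.
#' @param n_volumes number of volumes in the run.
#' @param phase trial phase defining the condition interval.
#' @return character vector of length `n_volumes` with values `"good"`,
#'   `"bad"`, `"rest"`.
#' @export
condition_labels <- function(schedule, run, TR = 2, n_volumes = 330,
                             phase = "decision") {
  sub <- schedule[schedule$run == run, ]
  onsets <- sub[[paste0("onset_", phase)]]
  durs <- sub[[paste0("dur_", phase)]]
  times <- (seq_len(n_volumes) - 1) * TR
  lab <- rep("rest", n_volumes)
  for (i in seq_along(onsets)) {
    inside <- times >= onsets[i] & times < onsets[i] + durs[i]
    lab[inside] <- sub$advice_label[i]
  }
  lab
}

#' Simulate latent VAR dynamics and observed BOLD for a group of subjects
#'
#' For each subject and run, a latent neural VAR(1) process is simulated on
#' the TR grid with condition-dependent coefficients
#' `x_t = A[condition(t)] x_{t-1} + drive_t + w_t`, where the condition of a
#' time point is taken from the decision phase covering it (and the `rest`
#' matrix applies between trials). A boxcar stimulus drive is applied to all
#' ROIs during decision phases. Each ROI's latent series is zero-order-held to
#' a fine grid and passed through the balloon hemodynamic forward model with
#' ROI-specific parameters, sampled at TR, and corrupted with observation
#' noise.
#'
#' @param net a [ground_truth_network()] with conditions matching the labels
#'   produced by the schedule (plus `"rest"`).
#' @param schedule an `event_schedule` whose runs fit in
#'   `n_volumes * TR` seconds, or a list of one schedule per subject
#'   (per-participant trial randomization, as in the task itself; with a
#'   single shared schedule, trial placement becomes a group-level
#'   confound in group comparisons).
#' @param hemo `NULL` (the default) to draw subject- and region-specific
#'   balloon parameters with [draw_hemodynamic_params()] at coefficient of
#'   variation `hemo_cv` — HRF variability is a subject-level property, so
#'   it averages out of group contrasts; or a single
#'   [hemodynamic_params()] / list of per-ROI parameter sets applied to every
#'   subject.
#' @param hemo_cv coefficient of variation of the per-subject HRF draws
#'   (used when `hemo` is `NULL`).
#' @param n_subjects number of subjects to simulate.
#' @param TR repetition time, s.
#' @param n_volumes volumes per run.
#' @param drive_amplitude stimulus drive added to every ROI during decision
#'   phases.
#' @param obs_noise_frac observation noise SD as a fraction of each ROI's
#'   noise-free BOLD SD.
#' @param neural_gain scale mapping latent VAR activity (innovation-SD units)
#'   to the balloon model's neural input; keeps sustained negative
#'   excursions within the physiological domain where blood flow stays
#'   positive.
#' @param dt integration step for the hemodynamic forward model, s.
#' @param observe if `FALSE`, skip the hemodynamic observation stage and
#'   return latent series only (for studies of the modelling stages alone).
#' @param seed optional RNG seed.
#' @return object of class `"sim_dataset"`: list with `subjects` (each a list
#'   of runs, each with `latent`, `bold` (time x ROI matrices), `labels`),
#'   plus `net`, `schedule`, `TR`, `roi_labels`.
#' @export
simulate_network_dataset <- function(net, schedule, hemo = NULL,
                                     hemo_cv = 0.2,
                                     n_subjects = 12, TR = 2,
                                     n_volumes = 330,
                                     drive_amplitude = 1,
                                     obs_noise_frac = 0.1,
                                     neural_gain = 0.2,
                                     dt = 0.1, observe = TRUE,
                                     seed = NULL) {
  stopifnot(inherits(net, "ground_truth_network"))
  if (!is.null(seed)) set.seed(seed)
  schedules <- if (inherits(schedule, "event_schedule"))
    rep(list(schedule), n_subjects)
  else rep_len(schedule, n_subjects)
  for (sc in schedules)
    if (any(run_duration(sc) > n_volumes * TR))
      stop("schedule does not fit within n_volumes * TR")
  n <- net$n_rois
  per_subject_hemo <- is.null(hemo)
  if (!per_subject_hemo) {
    if (!is.null(hemo$epsilon)) hemo <- list(hemo)  # single param set
    hemo <- rep_len(hemo, n)
  }
  runs <- sort(unique(schedules[[1]]$run))
  sub_steps <- round(TR / dt)

  subjects <- vector("list", n_subjects)
  hemo_used <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    hemo_s <- if (per_subject_hemo) draw_hemodynamic_params(n, cv = hemo_cv)
              else hemo
    hemo_used[[s]] <- hemo_s
    run_list <- vector("list", length(runs))
    for (ri in seq_along(runs)) {
      lab <- condition_labels(schedules[[s]], runs[ri], TR, n_volumes)
      missing <- setdiff(unique(lab), names(net$A))
      if (length(missing))
        stop("network has no matrix for condition(s): ",
             paste(missing, collapse = ", "))
      x <- matrix(0, n_volumes, n)
      drive <- ifelse(lab == "rest", 0, drive_amplitude)
      innov <- matrix(stats::rnorm(n_volumes * n), n_volumes, n) *
        rep(net$innovation_sd, each = n_volumes)
      for (t in 2:n_volumes) {
        x[t, ] <- net$A[[lab[t]]] %*% x[t - 1, ] + drive[t] + innov[t, ]
      }
      if (any(!is.finite(x))) stop("latent simulation diverged")
      bold <- matrix(NA_real_, n_volumes, n)
      if (observe) {
        for (j in seq_len(n)) {
          u_fine <- rep(neural_gain * x[, j], each = sub_steps)
          y <- hemodynamic_forward(u_fine, hemo_s[[j]], dt = dt, TR = TR)
          y <- y[seq_len(n_volumes)]
          noise_sd <- obs_noise_frac * stats::sd(y)
          bold[, j] <- y + stats::rnorm(n_volumes, 0, noise_sd)
        }
      }
      colnames(x) <- colnames(bold) <- net$labels
      run_list[[ri]] <- list(latent = x, bold = bold, labels = lab,
                             run = runs[ri])
    }
    subjects[[s]] <- list(runs = run_list, subject = s)
  }
  structure(list(subjects = subjects, net = net, schedule = schedules,
                 TR = TR, roi_labels = net$labels, hemo = hemo_used),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset: %d subjects x %d runs, %d ROIs, %d volumes at TR=%gs\n",
    length(x$subjects), length(x$subjects[[1]]$runs), length(x$roi_labels),
    nrow(x$subjects[[1]]$runs[[1]]$bold), x$TR))
  invisible(x)
}
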