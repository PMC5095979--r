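#' Condition-specific path-weight samples for one simulated group
#'
#' Runs the per-subject analysis chain on a simulated dataset: per run,
#' z-score the BOLD columns, blind-deconvolve them to latent neural series
#' with the cubature Kalman filter, fit the time-varying dMVAR model, and
#' aggregate the coefficients over the time points of the requested
#' condition. Runs of the same subject are pooled under one subject id.
#'
#' @param dataset a [simulate_network_dataset()] result.
#' @param condition condition label to aggregate (e.g. `"bad"`).
#' @param runs which run indices to include.
#' @param lambda dMVAR forgetting factor.
#' @param source `"bold"` to run the full chain through deconvolution,
#'   `"latent"` to fit directly on the ground-truth latent series (for
#'   testing the modelling stages in isolation).
#' @param config a [ckf_config()] for the deconvolution step.
#' @param group group name stored with the samples.
#' @return a [aggregate_condition_weights()] result.
#' @export
group_path_weights <- function(dataset, condition = "bad", runs = 1,
                               lambda = 0.98,
                               source = c("bold", "latent"),
                               config = ckf_config(), group = NULL) {
  source <- match.arg(source)
  stopifnot(inherits(dataset, "sim_dataset"))
  fits <- list()
  labels <- list()
  subjects <- integer(0)
  for (s in seq_along(dataset$subjects)) {
    for (ri in runs) {
      rd <- dataset$subjects[[s]]$runs[[ri]]
      x <- if (source == "latent") {
        normalize_per_run(rd$latent)
      } else {
        z <- normalize_per_run(rd$bold)
        dec <- ckf_deconvolve(z, TR = dataset$TR, config = config)
        dec$latent
      }
      fits[[length(fits) + 1]] <- dmvar(x, lambda = lambda)
      labels[[length(labels) + 1]] <- rd$labels
      subjects <- c(subjects, s)
    }
  }
  aggregate_condition_weights(fits, labels, condition, group = group,
                              subjects = subjects)
}

#' End-to-end two-group effective-connectivity comparison
#'
#' Full pipeline on two simulated groups: blind deconvolution, time-varying
#' dMVAR fitting, condition-specific aggregation, edge-wise group comparison
#' with FDR control, and driver/hub summary.
#'
#' @param group_a,group_b [simulate_network_dataset()] results for the two
#'   groups (e.g. human- and machine-agent).
#' @param condition condition in which the groups are compared.
#' @param runs run indices entering the comparison.
#' @param q_threshold FDR threshold for edge significance.
#' @param method `"pooled"` or `"subject"` (see [compare_path_weights()]).
#' @param lambda dMVAR forgetting factor.
#' @param source `"bold"` (full chain) or `"latent"` (skip deconvolution).
#' @param config a [ckf_config()].
#' @return list with `comparison` (a `network_comparison`), `summary`
#'   (a `network_summary`), and the two `path_weight_samples`.
#' @export
advice_gc_pipeline <- function(group_a, group_b, condition = "bad",
                               runs = 1, q_threshold = 0.05,
                               method = c("pooled", "subject"),
                               lambda = 0.98,
                               source = c("bold", "latent"),
                               config = ckf_config()) {
  method <- match.arg(method)
  source <- match.arg(source)
  pa <- group_path_weights(group_a, condition, runs, lambda, source, config,
                           group = "a")
  pb <- group_path_weights(group_b, condition, runs, lambda, source, config,
                           group = "b")
  cmp <- compare_path_weights(pa, pb, q_threshold = q_threshold,
                              method = method)
  list(comparison = cmp, summary = summarize_network(cmp),
       samples_a = pa, samples_b = pb)
}

#' Simulate a two-group advice-taking connectivity study
#'
#' The study conditions of the simulated experiment: two agent groups
#' (human, machine) of `n_subjects` participants, each completing 2 runs of
#' 32 trials (50% hits, 10% correct rejections, 40% false alarms) observed
#' as 330 volumes at TR = 2 s; trial order is randomized per participant;
#' balloon-model HRF parameters are drawn per subject and region; the
#' ground-truth directed network is the two-driver topology of
#' [advice_study_networks()] with hub out-edges 0.5 (human) vs 0.3
#' (machine).
#'
#' @param seed integer seed controlling every random element.
#' @param n_subjects subjects per group.
#' @param observe simulate the BOLD observation stage (`FALSE` keeps only
#'   latent series, for studies of the modelling stages alone).
#' @param nets networks as returned by [advice_study_networks()].
#' @return list with elements `human` and `machine`
#'   ([simulate_network_dataset()] results) and `nets`.
#' @export
simulate_advice_study <- function(seed, n_subjects = 12, observe = TRUE,
                                  nets = advice_study_networks()) {
  sch <- lapply(seq_len(n_subjects), function(s)
    generate_trial_schedule(64, runs = 2, agent = "human",
                            seed = seed * 1000 + s))
  scm <- lapply(seq_len(n_subjects), function(s)
    generate_trial_schedule(64, runs = 2, agent = "machine",
                            seed = seed * 1000 + 100 + s))
  human <- simulate_network_dataset(nets$human, sch,
                                    n_subjects = n_subjects,
                                    observe = observe, seed = seed * 100 + 3)
  machine <- simulate_network_dataset(nets$machine, scm,
                                      n_subjects = n_subjects,
                                      observe = observe, seed = seed * 100 + 4)
  list(human = human, machine = machine, nets = nets)
}

#' One replicate of the driver-recovery study
#'
#' Simulates the two-group study with [simulate_advice_study()] and runs the
#' full analysis chain ([advice_gc_pipeline()]) on the bad-advice condition
#' of both runs, comparing groups at the subject level. The driver summary
#' uses `q_threshold = 0.08`: driver status is a conjunction of five
#' simultaneous edge tests, so the topology summary uses a slightly more
#' permissive threshold than single-edge reporting (see the vignette).
#'
#' @param seed replicate seed.
#' @param source `"bold"` (full chain through blind deconvolution) or
#'   `"latent"`.
#' @param q_threshold FDR threshold for the driver summary.
#' @param method comparison mode (see [compare_path_weights()]).
#' @param lambda dMVAR forgetting factor.
#' @param config a [ckf_config()].
#' @return list with `summary`, `comparison`, `recovered` (TRUE when the
#'   drivers are exactly the two true hubs, each with full out-degree and
#'   reciprocally connected), `false_drivers` (character).
#' @export
driver_recovery_replicate <- function(seed, source = c("bold", "latent"),
                                      q_threshold = 0.08,
                                      method = "subject", lambda = 0.98,
                                      config = ckf_config()) {
  source <- match.arg(source)
  study <- simulate_advice_study(seed, observe = source == "bold")
  res <- advice_gc_pipeline(study$human, study$machine, condition = "bad",
                            runs = c(1, 2), q_threshold = q_threshold,
                            method = method, lambda = lambda,
                            source = source, config = config)
  hubs <- study$nets$human$labels[c(1, 2)]
  smry <- res$summary
  reciprocal <- nrow(smry$reciprocal_pairs) > 0 &&
    any((smry$reciprocal_pairs$node1 %in% hubs) &
          (smry$reciprocal_pairs$node2 %in% hubs))
  res$recovered <- setequal(smry$drivers, hubs) && reciprocal
  res$false_drivers <- setdiff(smry$drivers, hubs)
  res
}
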