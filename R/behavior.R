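#' Summarize behavioural trial records
#'
#' Computes per-subject accuracy, advice utilization (proportion of trials on
#' which the advice was accepted) per advice label and run, mean response
#' time per cell, and monetary outcome (endowment minus the per-error
#' deduction times the error count). Empty advice x run cells yield `NA` and
#' are listed in the `missing_cells` attribute rather than silently reported
#' as 0.
#'
#' @param records trial-record data.frame as produced by
#'   [simulate_agent_responses()] (optionally with a `subject` column).
#' @param endowment initial endowment, dollars.
#' @param deduction_per_error dollars deducted per incorrect answer.
#' @return data.frame with one row per subject: `subject`, `agent`,
#'   `accuracy`, `utilization_<label>_run<r>`, `rt_<label>_run<r>`,
#'   `total_deduction`, `remaining`.
#' @export
summarize_behavior <- function(records, endowment = 40,
                               deduction_per_error = 0.30) {
  if (is.null(records$subject)) records$subject <- 1
  subjects <- unique(records$subject)
  labels <- c("good", "bad")
  runs <- sort(unique(records$run))
  missing_cells <- character(0)
  rows <- lapply(subjects, function(s) {
    d <- records[records$subject == s, ]
    row <- data.frame(subject = s, agent = d$agent[1],
                      accuracy = mean(d$correct),
                      stringsAsFactors = FALSE)
    for (lb in labels) for (r in runs) {
      cell <- d[d$advice_label == lb & d$run == r, ]
      un <- paste0("utilization_", lb, "_run", r)
      rn <- paste0("rt_", lb, "_run", r)
      if (nrow(cell) == 0) {
        row[[un]] <- NA_real_
        row[[rn]] <- NA_real_
        missing_cells <<- c(missing_cells,
                            sprintf("subject %s: %s run %s", s, lb, r))
      } else {
        row[[un]] <- mean(cell$decision == "accept")
        row[[rn]] <- mean(cell$response_time)
      }
    }
    n_err <- sum(!d$correct)
    row$total_deduction <- deduction_per_error * n_err
    row$remaining <- endowment - row$total_deduction
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "missing_cells") <- missing_cells
  out
}

anova_table <- function(effect, df, ss, F, p) {
  data.frame(effect = effect, df = df, sum_sq = ss, F = F, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-way between-subjects ANOVA
#'
#' Classical between/within variance decomposition across `k` groups, with
#' F on `(k - 1, N - k)` degrees of freedom.
#'
#' @param groups list of numeric samples, one per group (each `n >= 2`).
#' @return data.frame with rows for the group effect and residuals:
#'   `effect`, `df`, `sum_sq`, `F`, `p`.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations")
  d <- data.frame(value = unlist(groups),
                  group = factor(rep(seq_along(groups),
                                     vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  pv <- s[["Pr(>F)"]][1]
  if (s[["Sum Sq"]][1] < 1e-12 * max(1, sum(s[["Sum Sq"]]))) {
    Fv <- 0  # no between-group variability
    pv <- 1
  }
  anova_table(effect = c("group", "residuals"),
              df = s[["Df"]], ss = s[["Sum Sq"]],
              F = c(Fv, NA), p = c(pv, NA))
}

#' Mixed repeated-measures ANOVA (2 within x 1 between, two levels each)
#'
#' Balanced mixed-design ANOVA with two two-level within-subject factors and
#' one two-level between-subjects factor: sums of squares for the 7 effects
#' (3 main, 3 two-way, 1 three-way) against their proper error strata
#' (subject error for the between effect; subject x factor interaction
#' strata for within effects). With a single-level between factor the design
#' collapses to a pure repeated-measures 2 x 2 ANOVA.
#'
#' @param data data.frame with one row per subject x within-cell.
#' @param value,subject,within,between column names: `value` the response,
#'   `subject` the subject id, `within` the two within-factor columns,
#'   `between` the between-factor column.
#' @return data.frame (`effect`, `df`, `sum_sq`, `F`, `p`) including the
#'   error strata rows (named `error: ...`).
#' @export
mixed_anova <- function(data, value = "value", subject = "subject",
                        within = c("advice", "time"), between = "agent") {
  d <- data.frame(value = data[[value]],
                  subject = factor(data[[subject]]),
                  w1 = factor(data[[within[1]]]),
                  w2 = factor(data[[within[2]]]),
                  between = factor(data[[between]]))
  n_cells <- nlevels(d$w1) * nlevels(d$w2)
  counts <- table(d$subject)
  if (any(counts != n_cells) || anyNA(d$value))
    stop("design must be complete and balanced (every subject in all cells)")
  per_subj_between <- tapply(d$between, d$subject,
                             function(g) length(unique(g)))
  if (any(per_subj_between != 1))
    stop("each subject must belong to exactly one between-group")
  has_between <- nlevels(d$between) > 1
  form <- if (has_between)
    value ~ w1 * w2 * between + Error(subject / (w1 * w2))
  else
    value ~ w1 * w2 + Error(subject / (w1 * w2))
  fit <- stats::aov(form, data = d)
  s <- summary(fit)
  rows <- list()
  rename <- c(w1 = within[1], w2 = within[2], between = between)
  pretty <- function(term) {
    parts <- strsplit(trimws(term), ":")[[1]]
    paste(ifelse(parts %in% names(rename), rename[parts], parts),
          collapse = " x ")
  }
  for (stratum in names(s)) {
    tab <- s[[stratum]][[1]]
    terms <- rownames(tab)
    for (i in seq_along(terms)) {
      nm <- trimws(terms[i])
      eff <- if (nm == "Residuals")
        paste0("error: ", sub("Error: ", "", stratum))
      else pretty(nm)
      rows[[length(rows) + 1]] <-
        anova_table(eff, tab[["Df"]][i], tab[["Sum Sq"]][i],
                    if (nm == "Residuals") NA else tab[["F value"]][i],
                    if (nm == "Residuals") NA else tab[["Pr(>F)"]][i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' t-tests (independent, paired, one-sample)
#'
#' Thin wrapper with the conventions used throughout the package: two-sided
#' by default, exact degrees of freedom, pooled variance for the independent
#' case.
#'
#' @param a numeric sample.
#' @param b second sample (independent/paired) or a single constant
#'   (one-sample reference).
#' @param kind `"independent"`, `"paired"`, or `"one_sample"`.
#' @param alternative passed to [stats::t.test()].
#' @return list with `t`, `df`, `p`.
#' @export
ttests <- function(a, b = NULL, kind = c("independent", "paired",
                                         "one_sample"),
                   alternative = "two.sided") {
  kind <- match.arg(kind)
  zero_var <- function(x) length(unique(x)) == 1
  res <- switch(kind,
    independent = {
      if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per sample")
      if (zero_var(a) && zero_var(b)) stop("zero variance in both samples")
      stats::t.test(a, b, var.equal = TRUE, alternative = alternative)
    },
    paired = {
      if (length(a) != length(b)) stop("paired samples must match in length")
      dd <- a - b
      if (zero_var(dd)) {
        if (dd[1] == 0)  # identical samples: no evidence of a difference
          return(list(t = 0, df = length(a) - 1, p = 1))
        stop("zero variance of paired differences")
      }
      stats::t.test(a, b, paired = TRUE, alternative = alternative)
    },
    one_sample = {
      if (length(b) != 1) stop("one-sample test needs a single reference value")
      if (zero_var(a)) stop("zero variance sample")
      stats::t.test(a, mu = b, alternative = alternative)
    })
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Advisory distributional diagnostics
#'
#' Normality (Kolmogorov-Smirnov against a fitted normal, per group) and
#' variance homogeneity (Bartlett). Advisory only: results never gate any
#' computation.
#'
#' @param groups list of numeric samples.
#' @return data.frame of test names and p-values.
#' @export
behavior_diagnostics <- function(groups) {
  ks <- vapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    suppressWarnings(stats::ks.test(g, "pnorm", mean(g), stats::sd(g))$p.value)
  }, numeric(1))
  bart <- stats::bartlett.test(groups)$p.value
  data.frame(test = c(paste0("ks_normality_group", seq_along(groups)),
                      "bartlett_homogeneity"),
             p = c(ks, bart), stringsAsFactors = FALSE)
}
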