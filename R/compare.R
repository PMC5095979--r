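edge_names <- function(labels) {
  n <- length(labels)
  idx <- expand.grid(target = seq_len(n), source = seq_len(n))
  idx <- idx[idx$source != idx$target, c("source", "target")]
  idx <- idx[order(idx$source, idx$target), ]
  rownames(idx) <- NULL
  idx$name <- paste0(labels[idx$source], "->", labels[idx$target])
  idx
}

#' Aggregate dMVAR coefficients into condition-specific path-weight samples
#'
#' For every directed edge `j -> i` (self-edges excluded), collects the
#' time-varying coefficients at all time instants labelled with the requested
#' condition, concatenated across subjects, yielding a sample distribution of
#' condition-specific Granger path weights.
#'
#' The coefficient at index `t` of a fit maps time point `t` to `t + 1`;
#' labels (one per input time point) are applied to the coefficient whose
#' lagged (source) time point bears them, so condition intervals are shifted
#' by one sample relative to the target time, respecting lag-1 modelling.
#'
#' @param fits a single [dmvar()] fit or a list of fits (one per subject or
#'   subject-run).
#' @param labels character vector of condition labels per input time point
#'   (length `T`, matching each fit's input), or a list of such vectors
#'   parallel to `fits`.
#' @param condition the condition to select.
#' @param group optional group name stored with the samples.
#' @param subjects optional subject ids parallel to `fits`; defaults to the
#'   fit index. Fits sharing a subject id (several runs) are pooled within
#'   that subject.
#' @return object of class `"path_weight_samples"`: list with `samples`
#'   (named list per edge of coefficient values), `subject_id` (subject of
#'   each sample, per edge), `edges`, `condition`, `group`, `labels`,
#'   `n_per_subject`.
#' @export
aggregate_condition_weights <- function(fits, labels, condition,
                                        group = NULL, subjects = NULL) {
  if (inherits(fits, "dmvar")) fits <- list(fits)
  if (!is.list(labels)) labels <- list(labels)
  labels <- rep_len(labels, length(fits))
  if (is.null(subjects)) subjects <- seq_along(fits)
  stopifnot(length(subjects) == length(fits))
  roi_labels <- fits[[1]]$labels
  edges <- edge_names(roi_labels)
  any_present <- FALSE

  samples <- stats::setNames(vector("list", nrow(edges)), edges$name)
  subj_of <- list()
  for (k in seq_len(nrow(edges))) samples[[k]] <- numeric(0)
  subj_vec <- numeric(0)
  for (f in seq_along(fits)) {
    fit <- fits[[f]]
    lab <- labels[[f]]
    if (length(lab) != nrow(fit$coef) + 1)
      stop("label vector must have one entry per input time point")
    sel <- which(lab[seq_len(nrow(fit$coef))] == condition)
    if (length(sel) > 0) any_present <- TRUE
    for (k in seq_len(nrow(edges))) {
      vals <- fit$coef[sel, edges$target[k], edges$source[k]]
      samples[[k]] <- c(samples[[k]], vals)
    }
    subj_vec <- c(subj_vec, rep(subjects[f], length(sel)))
  }
  if (!any_present)
    stop(sprintf("condition '%s' absent from labels", condition))
  structure(list(samples = samples, subject_id = subj_vec, edges = edges,
                 condition = condition, group = group, labels = roi_labels,
                 n_per_subject = table(subj_vec)),
            class = "path_weight_samples")
}

#' @export
print.path_weight_samples <- function(x, ...) {
  cat(sprintf(
    "Path-weight samples: condition '%s'%s, %d edges, %d values/edge (%d subjects)\n",
    x$condition, if (!is.null(x$group)) paste0(", group '", x$group, "'")
    else "", length(x$samples), length(x$samples[[1]]),
    length(unique(x$subject_id))))
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the i-th
#' smallest p is `min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted q-values in the original order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Compare condition-specific path weights between two groups
#'
#' Edge-by-edge two-sample t-tests (pooled variance) between the path-weight
#' samples of two groups, with Benjamini-Hochberg FDR adjustment over the
#' full family of `n * (n - 1)` directed edges.
#'
#' `method = "pooled"` tests the pooled time-point samples directly (the
#' aggregation-of-coefficients reading). `method = "subject"` first averages
#' coefficients within subject and tests across subjects; pooled time points
#' are serially dependent, so the subject-level test is the calibrated
#' variant (see the package vignette).
#'
#' @param a,b `path_weight_samples` for the two groups (same edge set).
#' @param q_threshold FDR significance threshold.
#' @param method `"pooled"` or `"subject"`.
#' @return object of class `"network_comparison"`: data.frame with one row
#'   per directed edge (`source`, `target`, `mean_a`, `mean_b`, `t`, `df`,
#'   `p`, `q`, `significant`), with attributes `labels`, `groups`,
#'   `q_threshold`, `method`.
#' @export
compare_path_weights <- function(a, b, q_threshold = 0.05,
                                 method = c("pooled", "subject")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "path_weight_samples"),
            inherits(b, "path_weight_samples"))
  if (!identical(a$edges$name, b$edges$name) ||
      !identical(a$labels, b$labels))
    stop("the two groups must share the same edge set and ROI labels")
  edges <- a$edges
  get_sample <- function(pw, k) {
    if (method == "pooled") return(pw$samples[[k]])
    as.numeric(tapply(pw$samples[[k]], pw$subject_id, mean))
  }
  rows <- lapply(seq_len(nrow(edges)), function(k) {
    sa <- get_sample(a, k); sb <- get_sample(b, k)
    if (stats::var(sa) == 0 && stats::var(sb) == 0) {
      return(data.frame(source = a$labels[edges$source[k]],
                        target = a$labels[edges$target[k]],
                        mean_a = mean(sa), mean_b = mean(sb),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(sa, sb, var.equal = TRUE)
    data.frame(source = a$labels[edges$source[k]],
               target = a$labels[edges$target[k]],
               mean_a = mean(sa), mean_b = mean(sb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$t))
    warning(sprintf("%d edge(s) with zero variance in both groups excluded from the FDR family",
                    sum(is.na(out$t))))
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- bh_fdr(out$p[ok])
  out$significant <- !is.na(out$q) & out$q < q_threshold
  attr(out, "labels") <- a$labels
  attr(out, "groups") <- c(a = a$group, b = b$group)
  attr(out, "q_threshold") <- q_threshold
  attr(out, "method") <- method
  class(out) <- c("network_comparison", "data.frame")
  out
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(
    "Network comparison (%s), %d directed edges, q threshold %g, %d significant\n",
    attr(x, "method"), nrow(x), attr(x, "q_threshold"),
    sum(x$significant)))
  print.data.frame(cbind(x[x$significant, c("source", "target")],
                         round(x[x$significant,
                                 c("mean_a", "mean_b", "t", "p", "q")], 4)))
  invisible(x)
}

#' Summarize a network comparison into drivers and reciprocal pairs
#'
#' A node is a driver of the network when its significant outgoing edges
#' reach every other node (out-degree `n - 1` among significant edges). A
#' pair of nodes is reciprocal when both directed edges between them are
#' significant.
#'
#' @param cmp a [compare_path_weights()] result.
#' @return object of class `"network_summary"`: list with `drivers`
#'   (character), `out_degree` (named integer), `reciprocal_pairs`
#'   (data.frame), `edges` (significant edges data.frame), `n_rois`.
#' @export
summarize_network <- function(cmp) {
  stopifnot(inherits(cmp, "network_comparison"))
  labels <- attr(cmp, "labels")
  n <- length(labels)
  sig <- cmp[cmp$significant, , drop = FALSE]
  out_degree <- stats::setNames(integer(n), labels)
  tab <- table(factor(sig$source, levels = labels))
  out_degree[names(tab)] <- as.integer(tab)
  drivers <- names(out_degree)[out_degree == n - 1]
  pairs <- utils::combn(labels, 2)
  recips <- apply(pairs, 2, function(pr) {
    fwd <- any(sig$source == pr[1] & sig$target == pr[2])
    bwd <- any(sig$source == pr[2] & sig$target == pr[1])
    fwd && bwd
  })
  reciprocal_pairs <- data.frame(node1 = pairs[1, recips],
                                 node2 = pairs[2, recips],
                                 stringsAsFactors = FALSE)
  structure(list(drivers = drivers, out_degree = out_degree,
                 reciprocal_pairs = reciprocal_pairs,
                 edges = as.data.frame(sig), n_rois = n),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network summary over %d ROIs: %d significant edges\n",
              x$n_rois, nrow(x$edges)))
  cat("Out-degree:", paste(names(x$out_degree), x$out_degree, sep = "=",
                           collapse = ", "), "\n")
  cat("Drivers:", if (length(x$drivers)) paste(x$drivers, collapse = ", ")
      else "(none)", "\n")
  if (nrow(x$reciprocal_pairs))
    cat("Reciprocal pairs:",
        paste(x$reciprocal_pairs$node1, x$reciprocal_pairs$node2,
              sep = " <-> ", collapse = "; "), "\n")
  invisible(x)
}

#' Export a comparison as BrainNet-style node/edge files
#'
#' Writes `<prefix>.node` (columns x, y, z, color, size, label; color 2 for
#' drivers, 1 otherwise; size = out-degree + 1) and `<prefix>.edge` (the
#' n x n matrix of t-values for significant edges, 0 elsewhere, rows =
#' sources).
#'
#' @param cmp a [compare_path_weights()] result.
#' @param coords data.frame with columns `label`, `x`, `y`, `z` (MNI mm).
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_brainnet <- function(cmp, coords, prefix) {
  labels <- attr(cmp, "labels")
  stopifnot(all(labels %in% coords$label))
  coords <- coords[match(labels, coords$label), ]
  smry <- summarize_network(cmp)
  node <- data.frame(x = coords$x, y = coords$y, z = coords$z,
                     color = ifelse(labels %in% smry$drivers, 2, 1),
                     size = smry$out_degree + 1, label = labels)
  node_path <- paste0(prefix, ".node")
  utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- length(labels)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  sig <- cmp[cmp$significant, ]
  for (k in seq_len(nrow(sig)))
    W[sig$source[k], sig$target[k]] <- sig$t[k]
  edge_path <- paste0(prefix, ".edge")
  utils::write.table(W, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Spearman correlation between behaviour and path weights
#'
#' Rank correlation between a per-subject behavioural measure (advice
#' utilization) and the per-subject mean path weight of each edge.
#'
#' @param behavior numeric vector, one value per subject.
#' @param weights matrix or data.frame, subjects x edges, columns named by
#'   edge.
#' @return data.frame with `edge`, `rho`, `p`.
#' @export
correlate_behavior_connectivity <- function(behavior, weights) {
  weights <- as.matrix(weights)
  if (length(behavior) != nrow(weights))
    stop("behavior and weights must cover the same subjects")
  if (length(behavior) < 4)
    stop("need at least 4 subjects for rank correlation")
  out <- lapply(colnames(weights), function(e) {
    ct <- suppressWarnings(
      stats::cor.test(behavior, weights[, e], method = "spearman"))
    data.frame(edge = e, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
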