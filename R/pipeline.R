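#' Weight an EEG epoch by a channel chromosome
#'
#' Row-wise dot multiplication between the EEG and the binary chromosome:
#' channels with a gene of one keep their signal, channels with a gene of
#' zero become all-zero time series. The epoch keeps its full dimension so
#' the inverse operator never changes shape.
#'
#' @param y d x K EEG epoch.
#' @param chromosome logical/0-1 vector of length d.
#' @return d x K weighted epoch.
#' @export
weight_eeg <- function(y, chromosome) {
  y <- as.matrix(y)
  if (length(chromosome) != nrow(y))
    stop_mismatch("chromosome length", length(chromosome), nrow(y))
  y * as.numeric(as.logical(chromosome))
}

#' Full run configuration
#'
#' @param solver a [solver_config()].
#' @param ga a [ga_config()].
#' @param tois list of per-source [toi()] windows (one per optimized source;
#'   the number of objectives is `length(tois) + 1`).
#' @param epoch length-2 numeric `c(start, end)` s: the trial segment handed
#'   to the solver. Defaults to the span of the TOIs.
#' @param montage montage subset spec passed to [make_montage_mask()].
#' @param penalty_error localization-error penalty (mm) assigned to the
#'   degenerate all-zero chromosome so it never survives selection.
#' @return List of class `run_config`.
#' @export
run_config <- function(solver = solver_config(), ga = ga_config(),
                       tois = list(toi(0.25, 0.75)), epoch = NULL,
                       montage = "full", penalty_error = 1e6) {
  if (length(tois) < 1) stop("need at least one TOI", call. = FALSE)
  for (tw in tois) if (!inherits(tw, "toi")) stop("tois must be toi objects", call. = FALSE)
  if (is.null(epoch))
    epoch <- c(min(vapply(tois, `[[`, numeric(1), "start")),
               max(vapply(tois, `[[`, numeric(1), "end")))
  structure(list(solver = solver, ga = ga, tois = tois, epoch = epoch,
                 montage = montage, penalty_error = penalty_error),
            class = "run_config")
}

crop_epoch <- function(y, fs, epoch) {
  idx <- toi_samples(toi(epoch[1], epoch[2]), fs, ncol(y))
  y[, idx, drop = FALSE]
}

#' Evaluate one channel-subset candidate
#'
#' Computes the objective vector of a chromosome on one trial: the number of
#' selected channels followed by the localization error of each optimized
#' source (mm). The trial epoch is weighted by the chromosome, inverted with
#' the full-dimension operator, and each source is located as the argmax of
#' TOI-averaged power, compared to that source's ground-truth position. The
#' all-zero chromosome gets penalty objectives `(0, penalty, ...)`.
#'
#' @param chromosome logical/0-1 vector of length d.
#' @param trial an `eeg_trial` (see [simulate_trial()]).
#' @param leadfield_inverse [leadfield] used for inversion.
#' @param solver a [solver_config()].
#' @param tois list of per-source [toi()] windows.
#' @param epoch epoch bounds `c(start, end)` s (default: span of TOIs).
#' @param operator optional precomputed [make_inverse_operator()] result.
#' @param penalty_error penalty for the all-zero chromosome, mm.
#' @return Numeric objective vector of length `length(tois) + 1`.
#' @export
evaluate_candidate <- function(chromosome, trial, leadfield_inverse,
                               solver = solver_config(), tois, epoch = NULL,
                               operator = NULL, penalty_error = 1e6) {
  s <- length(tois)
  chromosome <- as.logical(chromosome)
  if (!any(chromosome)) return(c(0, rep(penalty_error, s)))
  if (is.null(epoch))
    epoch <- c(min(vapply(tois, `[[`, numeric(1), "start")),
               max(vapply(tois, `[[`, numeric(1), "end")))
  if (is.null(operator))
    operator <- make_inverse_operator(leadfield_inverse, solver)
  y_epoch <- crop_epoch(trial$y, trial$fs, epoch)
  est <- apply_inverse(operator, weight_eeg(y_epoch, chromosome))
  errs <- vapply(seq_len(s), function(i) {
    loc <- estimate_location(est$x_hat, leadfield_inverse$source_positions,
                             tois[[i]], trial$fs, epoch_start = epoch[1])
    loc_error(trial$sources[[i]]$position, loc$estimated_position)
  }, numeric(1))
  c(sum(chromosome), errs)
}

#' Extract the pseudo-Pareto front from a candidate log
#'
#' For each channel count present in the log, the best-found candidate: the
#' one minimizing the mean of the per-source localization errors (for one
#' source, the error itself). Ties break by earliest generation, then by
#' lexicographically smallest bitstring. The degenerate zero-channel row is
#' excluded.
#'
#' @param candidate_log an [evolve()] result or its `log` data.frame.
#' @param s number of optimized sources.
#' @return Data.frame of class `pseudo_pareto_front`: one row per channel
#'   count with `n_channels`, `bitstring`, `generation`, per-source errors
#'   and `mean_locE`, sorted by channel count.
#' @export
extract_pseudo_pareto <- function(candidate_log, s) {
  log <- if (inherits(candidate_log, "candidate_log")) candidate_log$log
         else candidate_log
  if (nrow(log) == 0) stop("empty candidate log", call. = FALSE)
  err_cols <- paste0("obj_", 1 + seq_len(s))
  if (!all(err_cols %in% names(log)))
    stop("log lacks the expected objective columns", call. = FALSE)
  log <- log[log$n_channels > 0, , drop = FALSE]
  errs <- as.matrix(log[, err_cols, drop = FALSE])
  mean_err <- rowMeans(errs)
  ord <- order(log$n_channels, mean_err, log$generation, log$bitstring)
  log <- log[ord, , drop = FALSE]
  mean_err <- mean_err[ord]
  first <- !duplicated(log$n_channels)
  front <- data.frame(n_channels = log$n_channels[first],
                      bitstring = log$bitstring[first],
                      generation = log$generation[first],
                      stringsAsFactors = FALSE)
  front <- cbind(front, stats::setNames(
    as.data.frame(as.matrix(log[first, err_cols, drop = FALSE])),
    paste0("locE_", seq_len(s))))
  front$mean_locE <- mean_err[first]
  rownames(front) <- NULL
  class(front) <- c("pseudo_pareto_front", "data.frame")
  front
}

#' Run the channel-selection optimization on one trial
#'
#' The outer loop of the methodology: NSGA-II proposes channel chromosomes,
#' each candidate weights the trial EEG, the inverse solver reconstructs the
#' sources from the full-dimension weighted epoch, and the per-source
#' localization errors plus channel count form the objective vector. The
#' all-channel baseline (every montage channel selected) is always evaluated,
#' logged as a generation-0 row and returned separately; the pseudo-Pareto
#' front is extracted from the complete log.
#'
#' @param trial an `eeg_trial`.
#' @param leadfield_inverse inversion [leadfield].
#' @param config a [run_config()].
#' @return List of class `optimization_result`: `candidate_log`, `front`,
#'   `baseline` (list with `chromosome`, `objectives`, `mean_locE`), `mask`,
#'   `config`.
#' @export
run_optimization <- function(trial, leadfield_inverse, config = run_config()) {
  mask <- make_montage_mask(leadfield_inverse, config$montage)$included
  if (length(mask) != nrow(trial$y))
    stop_mismatch("trial channel count", nrow(trial$y), length(mask))
  s <- length(config$tois)
  operator <- make_inverse_operator(leadfield_inverse, config$solver)
  eval_fn <- function(bits)
    evaluate_candidate(bits, trial, leadfield_inverse, config$solver,
                       config$tois, epoch = config$epoch, operator = operator,
                       penalty_error = config$penalty_error)
  res <- evolve(eval_fn, n_genes = length(mask), config = config$ga,
                mask = mask)
  base_obj <- eval_fn(mask)
  base_row <- data.frame(generation = 0L, bitstring = bits_to_string(mask),
                         n_channels = sum(mask), stringsAsFactors = FALSE)
  base_row <- cbind(base_row, stats::setNames(
    as.data.frame(t(base_obj)), paste0("obj_", seq_along(base_obj))))
  res$log <- rbind(base_row, res$log)
  front <- extract_pseudo_pareto(res, s)
  baseline <- list(chromosome = mask, objectives = base_obj,
                   mean_locE = mean(base_obj[-1]))
  structure(list(candidate_log = res, front = front, baseline = baseline,
                 mask = mask, config = config),
            class = "optimization_result")
}

#' Summarize optimization results across trials
#'
#' Reproduces the layout of the dataset-level result tables: per channel
#' count, the mean and sample standard deviation (n - 1 denominator) of the
#' front localization error across trials, and the accuracy index against
#' the paired all-channel baseline.
#'
#' @param fronts list of per-trial [extract_pseudo_pareto()] fronts.
#' @param baselines numeric vector of per-trial baseline mean localization
#'   errors (mm), paired with `fronts`.
#' @return Data.frame with `n_channels`, `n_trials`, `mean_locE`, `sd_locE`,
#'   `accuracy_index`.
#' @export
summarize_dataset <- function(fronts, baselines) {
  if (length(fronts) != length(baselines))
    stop("fronts and baselines must be paired per trial", call. = FALSE)
  if (length(fronts) == 0) stop("need at least one trial", call. = FALSE)
  counts <- sort(unique(unlist(lapply(fronts, `[[`, "n_channels"))))
  rows <- lapply(counts, function(ch) {
    errs <- numeric(0); base <- numeric(0)
    for (i in seq_along(fronts)) {
      hit <- fronts[[i]]$n_channels == ch
      if (any(hit)) {
        errs <- c(errs, fronts[[i]]$mean_locE[hit][1])
        base <- c(base, baselines[i])
      }
    }
    data.frame(n_channels = ch, n_trials = length(errs),
               mean_locE = mean(errs),
               sd_locE = if (length(errs) > 1) stats::sd(errs) else 0,
               accuracy_index = accuracy_index(errs, base))
  })
  do.call(rbind, rows)
}

#' Plot a pseudo-Pareto front against the all-channel baseline
#'
#' Mean localization error (with +/- sd band when summarized across trials)
#' per channel count, plus a horizontal baseline line.
#'
#' @param summary a [summarize_dataset()] table (or a single-trial front).
#' @param baseline baseline mean localization error, mm.
#' @param ... passed to [graphics::plot()].
#' @export
plot_front <- function(summary, baseline = NULL, ...) {
  x <- summary$n_channels
  y <- if (!is.null(summary$mean_locE)) summary$mean_locE else summary$locE_1
  graphics::plot(x, y, type = "b", pch = 16,
                 xlab = "number of channels",
                 ylab = "mean localization error (mm)", ...)
  if (!is.null(summary$sd_locE)) {
    lo <- y - summary$sd_locE; hi <- y + summary$sd_locE
    graphics::polygon(c(x, rev(x)), c(lo, rev(hi)), border = NA,
                      col = grDevices::adjustcolor("steelblue", 0.25))
  }
  if (!is.null(baseline))
    graphics::abline(h = baseline, lty = 2, col = "firebrick")
  invisible(summary)
}
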