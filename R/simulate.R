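#' Gaussian-windowed sinusoidal source time course
#'
#' Evaluates `x(t) = exp(-0.5 ((t - c)/sigma)^2) * sin(2 pi f t)` at each
#' sample time, the canonical ground-truth waveform for transient oscillatory
#' cortical activity: a sinusoid at frequency `f` Hz under a Gaussian
#' envelope centered at `c` s with width `sigma` s.
#'
#' @param spec a [source_spec()] (or any list with `center`, `sigma`,
#'   `frequency`).
#' @param t numeric vector of sample times, s (non-empty, non-decreasing).
#' @return Numeric vector of the same length as `t`; always within `[-1, 1]`.
#' @export
#' @examples
#' t <- seq(0, 3.5, by = 1 / 200)
#' x <- source_timecourse(source_spec(center = 0.5, frequency = 19), t)
source_timecourse <- function(spec, t) {
  if (length(t) == 0 || is.unsorted(t)) stop("t must be non-empty and monotone", call. = FALSE)
  if (spec$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (spec$frequency <= 0) stop("frequency must be > 0", call. = FALSE)
  exp(-0.5 * ((t - spec$center) / spec$sigma)^2) * sin(2 * pi * spec$frequency * t)
}

#' Source activity specification
#'
#' @param region region name (`"occipital"`, `"sensorimotor"`, `"frontal"`).
#' @param vertex_index index into the source space (may be `NA` before
#'   placement).
#' @param position length-3 position, mm (may be `NULL` before placement).
#' @param center Gaussian window center, s.
#' @param sigma Gaussian window width, s.
#' @param frequency sinusoid frequency, Hz.
#' @return A list of class `source_spec`.
#' @export
source_spec <- function(region = "occipital", vertex_index = NA_integer_,
                        position = NULL, center = 0.5, sigma = 0.12,
                        frequency = 19) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (frequency <= 0) stop("frequency must be > 0", call. = FALSE)
  structure(list(region = region, vertex_index = vertex_index,
                 position = position, center = center, sigma = sigma,
                 frequency = frequency), class = "source_spec")
}

#' Predefined candidate source positions per brain region
#'
#' Partitions the source space into three region sets (occipital,
#' sensorimotor, frontal), each holding 12 candidate vertices (6 per
#' hemisphere) from which trial-wise source positions are drawn. On the
#' spherical fixture the regions are defined spatially: occipital = most
#' posterior vertices, sensorimotor = vertices closest to the crown, frontal
#' = most anterior; hemispheres split on the x coordinate. Coordinate
#' convention: +x right, +y anterior, +z superior.
#'
#' @param leadfield the forward-model [leadfield].
#' @param per_hemisphere candidates per hemisphere and region (default 6).
#' @return Named list of integer vectors of vertex indices, classes
#'   `region_sets`.
#' @export
make_region_sets <- function(leadfield, per_hemisphere = 6) {
  pos <- leadfield$source_positions
  n <- nrow(pos)
  if (n < 6 * per_hemisphere)
    stop("source space too small to define region sets", call. = FALSE)
  taken <- rep(FALSE, n)
  pick <- function(score, hemi_sign) {
    ok <- which(!taken & sign(pos[, 1]) == hemi_sign)
    sel <- ok[order(score[ok], decreasing = TRUE)][seq_len(per_hemisphere)]
    taken[sel] <<- TRUE
    sel
  }
  scores <- list(occipital = -pos[, 2], sensorimotor = pos[, 3],
                 frontal = pos[, 2])
  sets <- lapply(scores, function(sc) sort(c(pick(sc, -1), pick(sc, 1))))
  for (s in sets) if (length(s) != 2 * per_hemisphere || anyDuplicated(s))
    stop("failed to build distinct region sets", call. = FALSE)
  structure(sets, class = "region_sets")
}

#' Randomly place one source per region
#'
#' Draws one vertex index uniformly from each region's predefined candidate
#' set. Deterministic given the seed.
#'
#' @param region_sets a [make_region_sets()] result (named list of candidate
#'   index vectors).
#' @param rng_seed integer seed.
#' @return Named integer vector, one vertex index per region.
#' @export
place_sources <- function(region_sets, rng_seed) {
  if (any(lengths(region_sets) == 0))
    stop("empty region set", call. = FALSE)
  local_seed(rng_seed, {
    picks <- vapply(region_sets, function(set) set[sample.int(length(set), 1)],
                    integer(1))
  })
  picks
}

#' Forward-project sources and add SNR-controlled noise
#'
#' Computes the clean EEG `y = M[, vertices] %*% x` and, unless `snr_db` is
#' `NULL`, adds zero-mean white Gaussian channel noise rescaled post hoc so
#' that the realized `10 log10(P_signal / P_noise)` equals `snr_db` exactly,
#' with power P the mean squared amplitude pooled over all channels and
#' samples. Exact rescaling makes error levels comparable across trials.
#'
#' @param x s x K matrix of source time courses.
#' @param vertices integer vector of s source-space indices.
#' @param leadfield forward [leadfield].
#' @param snr_db target signal-to-noise ratio in dB, or `NULL` for no noise.
#' @param rng_seed integer seed for the noise draw.
#' @return List with `y` (d x K), `y_clean` (d x K) and `noise` (d x K or
#'   NULL).
#' @export
project_and_add_noise <- function(x, vertices, leadfield, snr_db = 0,
                                  rng_seed = 1) {
  x <- as.matrix(x)
  if (length(vertices) != nrow(x))
    stop_mismatch("number of vertices", length(vertices), nrow(x))
  if (any(vertices < 1 | vertices > ncol(leadfield$matrix)))
    stop("vertex index out of range for lead field", call. = FALSE)
  y_clean <- leadfield$matrix[, vertices, drop = FALSE] %*% x
  if (is.null(snr_db)) {
    return(list(y = y_clean, y_clean = y_clean, noise = NULL))
  }
  local_seed(rng_seed, {
    e <- matrix(stats::rnorm(length(y_clean)), nrow(y_clean), ncol(y_clean))
  })
  p_sig <- mean(y_clean^2)
  p_e <- mean(e^2)
  noise <- e * sqrt(p_sig / (p_e * 10^(snr_db / 10)))
  list(y = y_clean + noise, y_clean = y_clean, noise = noise)
}

#' Default simulation configuration
#'
#' The study conditions of the ground-truth dataset: six Gaussian-windowed
#' sinusoidal sources over three regions, two activations per region.
#' Sources 1-3 (occipital 19 Hz, sensorimotor 10 Hz, frontal 7 Hz) are
#' centered at 0.5, 1 and 1.5 s; sources 4-6 repeat the same locations and
#' frequencies at 2, 2.5 and 3 s and act as structured interference. Window
#' width 0.12 s throughout, 200 Hz sampling, 3.5 s trials, 0 dB SNR.
#'
#' @param fs sampling rate, Hz.
#' @param duration trial duration, s.
#' @param snr_db trial SNR, dB (`NULL` = noiseless).
#' @param sigma Gaussian window width, s.
#' @return List of class `sim_config` with `sources` (list of
#'   [source_spec()]), `fs`, `duration`, `snr_db`.
#' @export
default_sim_config <- function(fs = 200, duration = 3.5, snr_db = 0,
                               sigma = 0.12) {
  regions <- c("occipital", "sensorimotor", "frontal")
  freqs <- c(19, 10, 7)
  centers <- c(0.5, 1, 1.5, 2, 2.5, 3)
  sources <- lapply(seq_along(centers), function(i) {
    j <- ((i - 1) %% 3) + 1
    source_spec(region = regions[j], center = centers[i], sigma = sigma,
                frequency = freqs[j])
  })
  structure(list(sources = sources, fs = fs, duration = duration,
                 snr_db = snr_db), class = "sim_config")
}

validate_sim_config <- function(config) {
  if (!is.list(config) || is.null(config$sources) || length(config$sources) == 0)
    stop("invalid simulation config: no sources", call. = FALSE)
  if (is.null(config$fs) || config$fs <= 0) stop("invalid fs", call. = FALSE)
  if (is.null(config$duration) || config$duration <= 0)
    stop("invalid duration", call. = FALSE)
  for (s in config$sources) {
    if (s$sigma <= 0 || s$frequency <= 0)
      stop("invalid source spec in config", call. = FALSE)
    if (!s$region %in% c("occipital", "sensorimotor", "frontal"))
      stop(sprintf("unknown region '%s' in config", s$region), call. = FALSE)
  }
  invisible(config)
}

#' Simulate one EEG trial
#'
#' Places each configured source at a randomly drawn vertex of its region
#' set (sources sharing a region within the trial share the drawn vertex),
#' evaluates the windowed-sinusoid time courses, forward-projects them and
#' adds SNR-controlled noise.
#'
#' @param leadfield forward [leadfield].
#' @param region_sets candidate vertices per region ([make_region_sets()]).
#' @param config a `sim_config` (see [default_sim_config()]).
#' @param seed integer trial seed.
#' @return List of class `eeg_trial`: `y` (d x K), `y_clean`, `x_true`
#'   (s x K), `sources` (placed [source_spec()]s), `fs`, `duration`,
#'   `snr_db`, `seed`.
#' @export
simulate_trial <- function(leadfield, region_sets, config = default_sim_config(),
                           seed = 1) {
  validate_sim_config(config)
  t <- seq(0, by = 1 / config$fs, length.out = round(config$duration * config$fs))
  placement <- place_sources(region_sets, rng_seed = seed)
  sources <- lapply(config$sources, function(s) {
    s$vertex_index <- unname(placement[[s$region]])
    s$position <- leadfield$source_positions[s$vertex_index, ]
    s
  })
  x <- do.call(rbind, lapply(sources, source_timecourse, t = t))
  vertices <- vapply(sources, `[[`, integer(1), "vertex_index")
  proj <- project_and_add_noise(x, vertices, leadfield,
                                snr_db = config$snr_db,
                                rng_seed = seed + 1L)
  structure(list(y = proj$y, y_clean = proj$y_clean, x_true = x,
                 sources = sources, fs = config$fs,
                 duration = config$duration, snr_db = config$snr_db,
                 seed = seed),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> %d channels x %d samples, %d sources, SNR %s dB\n",
              nrow(x$y), ncol(x$y), length(x$sources),
              if (is.null(x$snr_db)) "Inf (noiseless)" else format(x$snr_db)))
  invisible(x)
}

#' Generate the ground-truth synthetic EEG dataset
#'
#' Default conditions: 150 trials of six-source activity, per-trial random
#' placement over the predefined region sets, 3.5 s at 200 Hz (700 samples)
#' and 0 dB SNR. The returned manifest records every trial's seed, true
#' vertex indices and positions so any solver can be benchmarked against the
#' ground truth.
#'
#' @param leadfield_forward [leadfield] used for forward projection.
#' @param n_trials number of trials (default 150).
#' @param config a `sim_config` (see [default_sim_config()]).
#' @param master_seed integer; per-trial seeds are derived from it.
#' @param region_sets optional precomputed [make_region_sets()] result.
#' @return List of class `eeg_dataset`: `trials` (list of `eeg_trial`) and
#'   `manifest` (per-trial data.frame plus config echo).
#' @export
generate_dataset <- function(leadfield_forward, n_trials = 150,
                             config = default_sim_config(), master_seed = 1,
                             region_sets = NULL) {
  validate_sim_config(config)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (is.null(region_sets)) region_sets <- make_region_sets(leadfield_forward)
  local_seed(master_seed, {
    trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  })
  trials <- lapply(trial_seeds, function(s)
    simulate_trial(leadfield_forward, region_sets, config, seed = s))
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    data.frame(trial = i, seed = tr$seed,
               source = seq_along(tr$sources),
               region = vapply(tr$sources, `[[`, character(1), "region"),
               vertex = vapply(tr$sources, `[[`, integer(1), "vertex_index"),
               center = vapply(tr$sources, `[[`, numeric(1), "center"),
               sigma = vapply(tr$sources, `[[`, numeric(1), "sigma"),
               frequency = vapply(tr$sources, `[[`, numeric(1), "frequency"),
               x = vapply(tr$sources, function(s) s$position[1], numeric(1)),
               y = vapply(tr$sources, function(s) s$position[2], numeric(1)),
               z = vapply(tr$sources, function(s) s$position[3], numeric(1)))
  })
  manifest <- list(n_trials = n_trials, fs = config$fs,
                   duration = config$duration,
                   snr_db = config$snr_db, master_seed = master_seed,
                   sources = do.call(rbind, rows))
  structure(list(trials = trials, manifest = manifest), class = "eeg_dataset")
}

#' Write / read a simulated dataset as plain text
#'
#' One TSV per trial (`trial_0001.tsv`: the d x K EEG) plus
#' `trial_0001_xtrue.tsv` and a `manifest.json` with seeds, vertex indices,
#' positions and the noise configuration.
#'
#' @param dataset an `eeg_dataset` from [generate_dataset()].
#' @param path output directory.
#' @return `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$trials)) {
    tr <- dataset$trials[[i]]
    utils::write.table(tr$y, file.path(path, sprintf("trial_%04d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(tr$x_true,
                       file.path(path, sprintf("trial_%04d_xtrue.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  m <- dataset$manifest
  jsonlite::write_json(
    list(n_trials = m$n_trials, fs = m$fs, duration = m$duration,
         snr_db = m$snr_db, master_seed = m$master_seed, sources = m$sources),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @param path dataset directory written by [write_dataset()].
#' @return `read_dataset`: an `eeg_dataset` (trials carry no `y_clean`).
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json", call. = FALSE)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  src <- as.data.frame(m$sources)
  trials <- lapply(seq_len(m$n_trials), function(i) {
    y <- as.matrix(utils::read.table(
      file.path(path, sprintf("trial_%04d.tsv", i)), sep = "\t"))
    x_true <- as.matrix(utils::read.table(
      file.path(path, sprintf("trial_%04d_xtrue.tsv", i)), sep = "\t"))
    dimnames(y) <- dimnames(x_true) <- NULL
    rows <- src[src$trial == i, , drop = FALSE]
    sources <- lapply(seq_len(nrow(rows)), function(j)
      source_spec(region = rows$region[j],
                  vertex_index = as.integer(rows$vertex[j]),
                  position = c(rows$x[j], rows$y[j], rows$z[j]),
                  center = rows$center[j], sigma = rows$sigma[j],
                  frequency = rows$frequency[j]))
    structure(list(y = y, y_clean = NULL, x_true = x_true, sources = sources,
                   fs = m$fs, duration = m$duration, snr_db = m$snr_db,
                   seed = rows$seed[1]),
              class = "eeg_trial")
  })
  structure(list(trials = trials,
                 manifest = list(n_trials = m$n_trials, fs = m$fs,
                                 duration = m$duration, snr_db = m$snr_db,
                                 master_seed = m$master_seed, sources = src)),
            class = "eeg_dataset")
}
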