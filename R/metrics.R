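#' Time-of-interest window
#'
#' @param start window start, s (>= 0).
#' @param end window end, s (> start).
#' @return List of class `toi`.
#' @export
toi <- function(start, end) {
  if (start < 0 || end <= start) stop("need 0 <= start < end", call. = FALSE)
  structure(list(start = start, end = end), class = "toi")
}

# TOI -> 1-based sample indices, half-open [round(start*fs), round(end*fs))
# in 0-based sample coordinates; a boundary shared by two windows therefore
# belongs to the later one (no double counting). `offset` shifts the window
# into an epoch cropped at `offset` seconds.
toi_samples <- function(toi, fs, n_samples, offset = 0) {
  a <- round((toi$start - offset) * fs)
  b <- round((toi$end - offset) * fs)
  if (a < 0 || b > n_samples || b <= a)
    stop("empty or out-of-range TOI window", call. = FALSE)
  seq.int(a + 1L, b)
}

#' Locate the most active source within a time window
#'
#' Element-wise power `x_hat^2` is averaged over the TOI samples and the
#' source with the highest mean power is taken as the estimated location;
#' ties break to the lowest vertex index.
#'
#' @param x_hat n x K source estimate matrix (or a `source_estimate`).
#' @param source_positions n x 3 source positions, mm.
#' @param toi a [toi()].
#' @param fs sampling rate, Hz.
#' @param epoch_start trial time of the first sample of `x_hat`, s.
#' @return List of class `localization_result`: `estimated_vertex`,
#'   `estimated_position`.
#' @export
estimate_location <- function(x_hat, source_positions, toi, fs,
                              epoch_start = 0) {
  if (inherits(x_hat, "source_estimate")) x_hat <- x_hat$x_hat
  x_hat <- as.matrix(x_hat)
  if (nrow(x_hat) != nrow(source_positions))
    stop_mismatch("source count", nrow(x_hat), nrow(source_positions))
  idx <- toi_samples(toi, fs, ncol(x_hat), offset = epoch_start)
  mean_power <- rowMeans(x_hat[, idx, drop = FALSE]^2)
  v <- which.max(mean_power)   # ties -> lowest index
  structure(list(estimated_vertex = v,
                 estimated_position = as.numeric(source_positions[v, ])),
            class = "localization_result")
}

#' Localization error (mm)
#'
#' Euclidean distance between the ground-truth and the estimated source
#' positions.
#'
#' @param p_true,p_hat length-3 positions, mm.
#' @return Distance in mm (>= 0).
#' @export
#' @examples
#' loc_error(c(0, 0, 0), c(3, 4, 0))  # 5
loc_error <- function(p_true, p_hat) {
  if (!all(is.finite(p_true)) || !all(is.finite(p_hat)))
    stop("positions must be finite", call. = FALSE)
  sqrt(sum((as.numeric(p_true) - as.numeric(p_hat))^2))
}

#' Relative error between two reconstructed time courses
#'
#' `||x1 - x2|| / ||x1||`, with `x1` the reconstruction computed with the
#' highest number of electrodes (the reference).
#'
#' @param x1 reference time course (nonzero).
#' @param x2 comparison time course, same length.
#' @return Non-negative relative error.
#' @export
rel_error <- function(x1, x2) {
  if (length(x1) != length(x2))
    stop_mismatch("time course length", length(x2), length(x1))
  n1 <- sqrt(sum(x1^2))
  if (n1 == 0) stop("reference time course has zero norm", call. = FALSE)
  sqrt(sum((x1 - x2)^2)) / n1
}

#' Pearson correlation between two reconstructed time courses
#'
#' @param x1,x2 equal-length (>= 2), non-constant vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x1, x2) {
  if (length(x1) != length(x2))
    stop_mismatch("time course length", length(x2), length(x1))
  if (length(x1) < 2) stop("need at least 2 samples", call. = FALSE)
  if (stats::var(x1) == 0 || stats::var(x2) == 0)
    stop("zero-variance input", call. = FALSE)
  stats::cor(x1, x2)
}

#' Accuracy index of an optimized electrode subset
#'
#' Percentage of trials whose localization error with the subset is equal to
#' or lower than the paired all-channel baseline error for the same trial.
#' Ties count as success (exact `<=`, no tolerance).
#'
#' @param errors_subset per-trial localization errors with the subset, mm.
#' @param errors_allchannels paired per-trial baseline errors, mm.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' accuracy_index(c(1, 2, 3), c(2, 2, 2))  # 66.67
accuracy_index <- function(errors_subset, errors_allchannels) {
  if (length(errors_subset) != length(errors_allchannels))
    stop("accuracy index needs trial-paired vectors of equal length",
         call. = FALSE)
  if (length(errors_subset) == 0) stop("need at least one trial", call. = FALSE)
  100 * mean(errors_subset <= errors_allchannels)
}
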