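#' Inverse solver configuration
#'
#' @param method `"wmne"` (depth-weighted minimum-norm estimation) or
#'   `"sloreta"` (standardized low-resolution tomography), or the name of a
#'   solver registered with [register_solver()].
#' @param lambda_rule `"snr_based"` (default) sets the Tikhonov parameter
#'   from the assumed data SNR as `lambda = trace(M W^-1 M^T) / (d *
#'   10^(snr_db/10))`; `"fixed"` uses `lambda_value` directly.
#' @param lambda_value fixed regularization parameter (>= 0), used when
#'   `lambda_rule = "fixed"`.
#' @param depth_exponent wMNE depth-weighting exponent in `[0, 2]`; the
#'   weighting matrix is `W = diag(||m_i||^(2 * depth_exponent))` built from
#'   lead-field column norms, compensating the depth bias of the plain
#'   minimum-norm solution. `0` reduces wMNE to unweighted MNE.
#' @param snr_db assumed data SNR (dB) for the `snr_based` rule; defaults to
#'   0 dB, the simulator's noise level.
#' @param reference `"none"` (default) or `"average"`; with `"average"` an
#'   average-reference projector is applied to both the EEG and the lead
#'   field before inversion. The default is `"none"` because the channel
#'   selection pipeline encodes discarded channels as all-zero rows, and
#'   re-referencing would re-inject signal into them.
#' @return List of class `solver_config`.
#' @export
solver_config <- function(method = c("sloreta", "wmne"),
                          lambda_rule = c("snr_based", "fixed"),
                          lambda_value = 0, depth_exponent = 1,
                          snr_db = 0, reference = c("none", "average")) {
  method <- if (length(method) == 1) method else match.arg(method)
  lambda_rule <- match.arg(lambda_rule)
  reference <- match.arg(reference)
  if (lambda_value < 0) stop("lambda_value must be >= 0", call. = FALSE)
  if (depth_exponent < 0 || depth_exponent > 2)
    stop("depth_exponent must be in [0, 2]", call. = FALSE)
  structure(list(method = method, lambda_rule = lambda_rule,
                 lambda_value = lambda_value,
                 depth_exponent = depth_exponent, snr_db = snr_db,
                 reference = reference), class = "solver_config")
}

apply_reference <- function(M, reference) {
  if (reference == "average") M - matrix(colMeans(M), nrow(M), ncol(M), byrow = TRUE)
  else M
}

choose_lambda <- function(gram, config) {
  if (config$lambda_rule == "fixed") return(config$lambda_value)
  sum(diag(gram)) / (nrow(gram) * 10^(config$snr_db / 10))
}

# Solve (gram + lambda I) Z = B by Cholesky; falls back to the Moore-Penrose
# pseudo-inverse (flagged) when the system is singular at lambda = 0.
solve_spd <- function(gram, lambda, B) {
  K <- gram + diag(lambda, nrow(gram))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    list(Z = MASS::ginv(K) %*% B, fallback = TRUE)
  } else {
    list(Z = chol2inv(ch) %*% B, fallback = FALSE)
  }
}

#' Precompute a linear inverse operator
#'
#' Builds the n x d matrix mapping an EEG epoch to the source estimate for
#' the configured method, so repeated inversions of candidate-weighted
#' epochs reuse one factorization. For wMNE the operator is
#' `W^-1 M^T (M W^-1 M^T + lambda I)^-1`; for sLORETA the minimum-norm
#' operator `M^T (M M^T + lambda I)^-1` with each source row standardized by
#' `sqrt(R_ii)`, `R = M^T (M M^T + lambda I)^-1 M` (the resolution-derived
#' variance). Sources invisible to the montage (zero variance) get a zero
#' row and a recorded warning.
#'
#' @param leadfield the inversion [leadfield].
#' @param config a [solver_config()].
#' @return List of class `inverse_operator` with `K_op` (n x d), `method`,
#'   `lambda`, `fallback` flag.
#' @export
make_inverse_operator <- function(leadfield, config = solver_config()) {
  M <- apply_reference(leadfield$matrix, config$reference)
  d <- nrow(M)
  if (config$method == "wmne") {
    w <- colSums(M^2)^config$depth_exponent   # ||m_i||^(2*depth_exponent)
    if (any(w <= 0)) stop("lead field has an all-zero column", call. = FALSE)
    MR <- M * rep(1 / w, each = d)            # M W^-1
    gram <- tcrossprod(MR, M)                 # M W^-1 M^T
    lambda <- choose_lambda(gram, config)
    sol <- solve_spd(gram, lambda, diag(d))
    K_op <- t(MR) %*% sol$Z                   # W^-1 M^T (gram + lambda I)^-1
  } else if (config$method == "sloreta") {
    gram <- tcrossprod(M)
    lambda <- choose_lambda(gram, config)
    sol <- solve_spd(gram, lambda, diag(d))
    T_op <- t(M) %*% sol$Z                    # M^T (M M^T + lambda I)^-1
    r_diag <- rowSums(T_op * t(M))            # diag(M^T Kinv M)
    bad <- r_diag <= .Machine$double.eps * max(r_diag, 0)
    if (any(bad))
      warning(sprintf("%d source(s) invisible to the montage; standardized to 0",
                      sum(bad)))
    scale <- ifelse(bad, 0, 1 / sqrt(pmax(r_diag, .Machine$double.xmin)))
    K_op <- T_op * scale
  } else {
    plugin <- solver_registry[[config$method]]
    if (is.null(plugin))
      stop(sprintf("unknown inverse method '%s'", config$method), call. = FALSE)
    return(plugin(leadfield, config))
  }
  structure(list(K_op = K_op, method = config$method, lambda = lambda,
                 fallback = sol$fallback, reference = config$reference),
            class = "inverse_operator")
}

#' Apply a precomputed inverse operator to an epoch
#'
#' @param operator an [make_inverse_operator()] result.
#' @param y d x K EEG epoch (excluded channels as all-zero rows).
#' @return A `source_estimate`: list with `x_hat` (n x K), `method`,
#'   `lambda_used`.
#' @export
apply_inverse <- function(operator, y) {
  y <- as.matrix(y)
  if (nrow(y) != ncol(operator$K_op))
    stop_mismatch("epoch channel count", nrow(y), ncol(operator$K_op))
  y <- apply_reference(y, operator$reference)
  structure(list(x_hat = operator$K_op %*% y, method = operator$method,
                 lambda_used = operator$lambda), class = "source_estimate")
}

#' Depth-weighted minimum-norm source estimate (wMNE)
#'
#' Tikhonov-regularized minimum-norm estimation with diagonal depth
#' weighting: `x_hat = W^-1 M^T (M W^-1 M^T + lambda I)^-1 y`, where `W`
#' compensates the distance of deep sources from the electrodes.
#'
#' @param y d x K EEG epoch.
#' @param leadfield inversion [leadfield].
#' @param config a [solver_config()] (its `method` is ignored).
#' @return A `source_estimate`.
#' @export
wmne <- function(y, leadfield, config = solver_config(method = "wmne")) {
  config$method <- "wmne"
  apply_inverse(make_inverse_operator(leadfield, config), y)
}

#' Standardized low-resolution tomography source estimate (sLORETA)
#'
#' Minimum-norm estimate standardized by the square root of the
#' resolution-derived variance of each source. For a single noiseless dipole
#' the standardized power attains its maximum at the true source (zero
#' localization error), for any regularization strength.
#'
#' @inheritParams wmne
#' @return A `source_estimate`.
#' @export
sloreta <- function(y, leadfield, config = solver_config(method = "sloreta")) {
  config$method <- "sloreta"
  apply_inverse(make_inverse_operator(leadfield, config), y)
}

solver_registry <- new.env(parent = emptyenv())

#' Register a third-party inverse solver
#'
#' Plug-in point for additional distributed solvers (e.g. Bayesian
#' multiple-prior methods). `builder(leadfield, config)` must return an
#' `inverse_operator`-like object accepted by [apply_inverse()] (fields
#' `K_op`, `method`, `lambda`, `reference`).
#'
#' @param name method name used in [solver_config()].
#' @param builder operator-builder function.
#' @export
register_solver <- function(name, builder) {
  stopifnot(is.character(name), is.function(builder))
  assign(name, builder, envir = solver_registry)
  invisible(name)
}

#' Solve the EEG inverse problem (dispatcher)
#'
#' Dispatches a full-dimension weighted epoch (excluded channels as all-zero
#' rows) to the configured method without subsetting the lead field: zeroed
#' channels carry no information but the operator shape never changes.
#'
#' @param y_w d x K weighted epoch.
#' @param leadfield inversion [leadfield].
#' @param config a [solver_config()].
#' @return A `source_estimate`.
#' @export
solve_inverse <- function(y_w, leadfield, config = solver_config()) {
  apply_inverse(make_inverse_operator(leadfield, config), y_w)
}
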