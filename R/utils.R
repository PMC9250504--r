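#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

bits_to_string <- function(bits) {
  paste(as.integer(bits), collapse = "")
}

string_to_bits <- function(s) {
  as.integer(strsplit(s, "", fixed = TRUE)[[1]]) == 1L
}

#' Number of electrode combinations in an exhaustive search
#'
#' Size of the search space an exhaustive electrode-subset evaluation would
#' have to cover: `2^C - 1` inverse solutions for a single source and
#' `s * 2^C - 1` for `s` sources, with `C` candidate channels. For C = 128
#' this is about 3.4e38, which is why a genetic search is used instead.
#'
#' @param n_channels number of candidate channels C.
#' @param n_sources number of sources s (default 1).
#' @return The combination count as a double (exact only while representable).
#' @export
#' @examples
#' n_electrode_combinations(8)    # 255
#' n_electrode_combinations(128)  # ~3.4e38
n_electrode_combinations <- function(n_channels, n_sources = 1) {
  stopifnot(n_channels >= 1, n_sources >= 1)
  if (n_sources == 1) 2^n_channels - 1 else n_sources * 2^n_channels - 1
}

stop_mismatch <- function(what, got, want) {
  stop(sprintf("%s: expected %s, got %s", what, want, got), call. = FALSE)
}
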