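#' Montage constraint mask
#'
#' Builds a boolean channel-inclusion mask constraining the optimization
#' search space to a sub-montage, mirroring searches restricted to e.g. the
#' 128 scalp electrodes or the 60 electrodes of the 10-10 standard within a
#' high-density layout. The mask never changes the lead-field dimensions:
#' constrained channels are handled downstream by clamping their genes to
#' zero, because the inverse solution is always computed with the full
#' operator.
#'
#' `subset_spec` may be `"full"` (all channels), an explicit character vector
#' of electrode labels, or the name of a shipped sub-montage list
#' (`"sub128"`, `"sub60"`, defined for the 231-channel spherical fixture;
#' one label per line under `inst/extdata/`).
#'
#' @param leadfield a [leadfield].
#' @param subset_spec `"full"`, `"sub128"`, `"sub60"`, or a label vector.
#' @return An object of class `montage_mask`: list with `name` and logical
#'   `included` of length d.
#' @export
#' @examples
#' lf <- build_spherical_leadfield(16, 40, seed = 1)
#' make_montage_mask(lf, "full")
#' make_montage_mask(lf, c("E001", "E005", "E009"))
make_montage_mask <- function(leadfield, subset_spec = "full") {
  labels <- leadfield$channel_labels
  if (length(subset_spec) == 1 && subset_spec %in% c("full", "sub128", "sub60")) {
    name <- subset_spec
    if (subset_spec == "full") {
      wanted <- labels
    } else {
      file <- system.file("extdata", sprintf("montage_%s.txt", subset_spec),
                          package = "eegselect", mustWork = TRUE)
      wanted <- readLines(file)
    }
  } else {
    name <- "custom"
    wanted <- as.character(subset_spec)
  }
  missing <- setdiff(wanted, labels)
  if (length(missing) > 0)
    stop(sprintf("unknown electrode label(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  included <- labels %in% wanted
  if (sum(included) < 2)
    stop("montage mask must include at least 2 channels", call. = FALSE)
  structure(list(name = name, included = included), class = "montage_mask")
}

#' @export
print.montage_mask <- function(x, ...) {
  cat(sprintf("<montage_mask> '%s': %d of %d channels\n",
              x$name, sum(x$included), length(x$included)))
  invisible(x)
}
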