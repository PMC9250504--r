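#' Write a lead-field archive
#'
#' Serializes one or more resolutions of a head model to a plain-text archive
#' directory. The archive holds the datasets `M` (d x n gain matrix),
#' `chanlocs` (d x 3), `chanlabels`, `srcpos` (n x 3) and `srcori` (n x 3) as
#' TSV/label files, one `M`/`srcpos`/`srcori` triplet per resolution, plus a
#' `meta.json` descriptor. Published head-model archives use the same dataset
#' names inside an HDF5 container; this text layout mirrors that field naming
#' so converted models can be dropped in.
#'
#' @param leadfields named list of [leadfield] objects; names are resolution
#'   tags, conventionally `high` (dense source grid, forward simulation) and
#'   `inverse` (coarser grid used to compute inverse solutions so forward and
#'   inverse grids differ).
#' @param path directory to create.
#' @return `path`, invisibly.
#' @seealso [load_leadfield()]
#' @export
write_leadfield_archive <- function(leadfields, path) {
  if (is.null(names(leadfields)) || any(!nzchar(names(leadfields))))
    stop("leadfields must be a named list (resolution tags)", call. = FALSE)
  lf1 <- leadfields[[1]]
  for (lf in leadfields) {
    if (!inherits(lf, "leadfield")) stop("entries must be leadfield objects", call. = FALSE)
    if (!identical(lf$channel_labels, lf1$channel_labels))
      stop("all resolutions must share the same channel set", call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, file)
    utils::write.table(m, file.path(path, file), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  write_mat(lf1$channel_positions, "chanlocs.tsv")
  writeLines(lf1$channel_labels, file.path(path, "chanlabels.txt"))
  for (res in names(leadfields)) {
    lf <- leadfields[[res]]
    write_mat(lf$matrix, sprintf("M_%s.tsv", res))
    write_mat(lf$source_positions, sprintf("srcpos_%s.tsv", res))
    write_mat(lf$source_orientations, sprintf("srcori_%s.tsv", res))
  }
  jsonlite::write_json(
    list(format = "eegselect-leadfield-archive", version = 1L,
         resolutions = as.list(names(leadfields))),
    file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a lead field from an archive
#'
#' Reads one resolution of a lead-field archive written by
#' [write_leadfield_archive()]. By convention the `high` resolution is used
#' for forward simulation and the `inverse` resolution for source
#' reconstruction, so the two computations never share a source grid.
#'
#' @param path archive directory.
#' @param resolution which stored resolution to load, typically `"high"` or
#'   `"inverse"`.
#' @return A [leadfield].
#' @export
load_leadfield <- function(path, resolution = c("high", "inverse")) {
  resolution <- if (length(resolution) == 1) resolution else match.arg(resolution)
  if (!dir.exists(path)) stop(sprintf("archive not found: %s", path), call. = FALSE)
  need <- function(file, field) {
    fp <- file.path(path, file)
    if (!file.exists(fp))
      stop(sprintf("malformed lead-field archive: missing field '%s' (%s)",
                   field, file), call. = FALSE)
    fp
  }
  read_mat <- function(file, field)
    as.matrix(utils::read.table(need(file, field), sep = "\t", header = FALSE))
  labels <- readLines(need("chanlabels.txt", "chanlabels"))
  lf <- leadfield(
    matrix = read_mat(sprintf("M_%s.tsv", resolution), "M"),
    channel_labels = labels,
    channel_positions = read_mat("chanlocs.tsv", "chanlocs"),
    source_positions = read_mat(sprintf("srcpos_%s.tsv", resolution), "srcpos"),
    source_orientations = read_mat(sprintf("srcori_%s.tsv", resolution), "srcori"))
  dimnames(lf$matrix) <- NULL
  dimnames(lf$channel_positions) <- NULL
  dimnames(lf$source_positions) <- NULL
  dimnames(lf$source_orientations) <- NULL
  lf
}
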