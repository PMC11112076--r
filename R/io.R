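# Epoched-data container: flat little-endian float64 array plus JSON
# sidecar (`<path>.json`) carrying dims, fs, times, labels, units and
# provenance metadata.  Round trips are bit-exact.

#' Write / read epoched data (binary array + JSON sidecar)
#'
#' `write_epochs` stores the voltage array as little-endian float64 in
#' column-major (channels fastest) order at `path` and the schema
#' (`dims`, `fs`, `t_start_ms`, `labels`, `units`, `meta`) at
#' `<path>.json`.  `read_epochs` validates the schema and reports missing
#' fields by name; unknown sidecar fields are preserved verbatim in
#' `meta$foreign` and written back by `write_epochs`.
#'
#' @param data an `epoched_data`.
#' @param path path of the binary array file.
#' @return `read_epochs` returns an `epoched_data`; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(data, path) {
  stopifnot(inherits(data, "epoched_data"))
  meta <- data$meta
  foreign <- meta$foreign
  meta$foreign <- NULL
  sidecar <- list(format = "tmseegsim-epochs-v1",
                  dims = dim(data$data), fs = data$fs,
                  t_start_ms = data$times[1], labels = data$labels,
                  units = data$units, meta = meta)
  if (!is.null(foreign)) sidecar <- utils::modifyList(sidecar, foreign)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(data$data), con, size = 8, endian = "little")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a lead field (binary gain matrix + JSON sidecar)
#'
#' Same container convention as [write_epochs()]: the gain matrix as
#' little-endian float64 at `path`, with dims, channel labels, the
#' average-reference flag and a montage fingerprint in `<path>.json`.
#'
#' @param leadfield a `leadfield` from [compute_leadfield()].
#' @param path path of the binary file.
#' @return `read_leadfield` returns a list with `gain`, `labels`,
#'   `average_reference`, `montage_fingerprint`.
#' @export
write_leadfield <- function(leadfield, path) {
  stopifnot(inherits(leadfield, "leadfield"))
  sidecar <- list(format = "tmseegsim-leadfield-v1",
                  dims = dim(leadfield$gain),
                  labels = leadfield$montage$label,
                  average_reference = leadfield$average_reference,
                  montage_fingerprint =
                    config_fingerprint(leadfield$montage),
                  units = "uV per unit dipole moment")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(leadfield$gain), con, size = 8, endian = "little")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  for (field in c("dims", "labels"))
    if (is.null(sc[[field]]))
      stop("sidecar schema error: missing field '", field, "'")
  dims <- as.integer(sc$dims)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
  list(gain = matrix(v, dims[1], dims[2]),
       labels = as.character(sc$labels),
       average_reference = isTRUE(sc$average_reference),
       montage_fingerprint = sc$montage_fingerprint)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar_path)) stop("missing JSON sidecar: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("dims", "fs", "t_start_ms", "labels", "units")) {
    if (is.null(sc[[field]]))
      stop("sidecar schema error: missing field '", field, "'")
  }
  dims <- as.integer(sc$dims)
  if (length(dims) != 3) stop("sidecar schema error: dims must have length 3")
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(v) != n)
    stop("array file truncated: expected ", n, " values, got ", length(v))
  known <- c("format", "dims", "fs", "t_start_ms", "labels", "units", "meta")
  meta <- if (is.null(sc$meta)) list() else as.list(sc$meta)
  extra <- sc[setdiff(names(sc), known)]
  if (length(extra)) meta$foreign <- extra
  x <- epoched_data(array(v, dim = dims), as.numeric(sc$fs),
                    as.numeric(sc$t_start_ms),
                    as.character(sc$labels), meta = meta)
  x$units <- sc$units
  x
}
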