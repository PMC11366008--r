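# On-disk container for epoched datasets: one directory per subject holding a
# JSON sidecar (sampling parameters, valence labels, montage) and the epoch
# tensor as raw little-endian float64 in column-major order with dimensions
# [trials, channels, samples]. The round trip is bit-exact.

#' Save an epoched dataset to a directory container
#'
#' @param epochs list of [epoch_set()] objects.
#' @param meta optional [subject_meta()] table; written as `metadata.csv`.
#' @param path directory to create.
#' @param overwrite overwrite an existing container? Default `FALSE`.
#' @return `path`, invisibly.
#' @seealso [load_dataset()]
#' @export
save_dataset <- function(epochs, meta = NULL, path, overwrite = FALSE) {
  if (inherits(epochs, "epoch_set")) epochs <- list(epochs)
  if (dir.exists(path)) {
    if (!overwrite)
      stopf("'%s' already exists; use overwrite = TRUE to replace it", path)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  for (ep in epochs) {
    sdir <- file.path(path, ep$subject_id)
    dir.create(sdir)
    side <- list(
      subject_id = ep$subject_id,
      srate = ep$srate, t0 = ep$t0,
      dims = dim(ep$data),
      valence = ep$valence,
      montage = list(
        labels = ep$montage$labels,
        positions = if (is.null(ep$montage$positions)) NULL else
          list(x = ep$montage$positions$x, y = ep$montage$positions$y)),
      dtype = "float64-le", order = "column-major")
    jsonlite::write_json(side, file.path(sdir, "sidecar.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    con <- file(file.path(sdir, "epochs.bin"), "wb")
    writeBin(as.vector(ep$data), con, size = 8L, endian = "little")
    close(con)
  }
  if (!is.null(meta))
    utils::write.csv(as.data.frame(meta), file.path(path, "metadata.csv"),
                     row.names = FALSE)
  invisible(path)
}

read_sidecar <- function(sfile) {
  side <- tryCatch(jsonlite::read_json(sfile, simplifyVector = TRUE),
                   error = function(e)
                     stopf("malformed sidecar '%s': %s", sfile,
                           conditionMessage(e)))
  for (field in c("subject_id", "srate", "t0", "dims", "valence", "montage"))
    if (is.null(side[[field]]))
      stopf("sidecar '%s' is missing field '%s'", sfile, field)
  side
}

#' Load an epoched dataset from a directory container
#'
#' Reads every subject directory under `path` and, if present,
#' `metadata.csv`. Subjects present in the signal container but absent from
#' the metadata table are returned with `NA` scores and flagged with a
#' warning.
#'
#' @param path container directory written by [save_dataset()].
#' @return A list with elements `epochs` (list of [epoch_set()]) and `meta`
#'   (a [subject_meta()] table or `NULL`).
#' @export
load_dataset <- function(path) {
  if (!dir.exists(path)) stopf("no such container directory: '%s'", path)
  subdirs <- list.dirs(path, recursive = FALSE)
  epochs <- list()
  for (sdir in subdirs) {
    sfile <- file.path(sdir, "sidecar.json")
    bfile <- file.path(sdir, "epochs.bin")
    if (!file.exists(sfile)) next
    side <- read_sidecar(sfile)
    dims <- as.integer(side$dims)
    if (length(side$montage$labels) != dims[2])
      stopf("'%s': sidecar declares %d channels but montage has %d labels",
            sfile, dims[2], length(side$montage$labels))
    nexp <- prod(dims)
    if (!file.exists(bfile)) stopf("missing epoch data file '%s'", bfile)
    if (file.size(bfile) != nexp * 8L)
      stopf("'%s': expected %d float64 values (%d bytes) but file has %d bytes",
            bfile, nexp, nexp * 8L, file.size(bfile))
    con <- file(bfile, "rb")
    vals <- readBin(con, "double", n = nexp, size = 8L, endian = "little")
    close(con)
    pos <- side$montage$positions
    mont <- montage(side$montage$labels,
                    if (is.null(pos)) NULL else data.frame(x = pos$x, y = pos$y))
    epochs[[side$subject_id]] <- epoch_set(
      subject_id = side$subject_id,
      data = array(vals, dim = dims),
      valence = side$valence, srate = side$srate, t0 = side$t0,
      montage = mont)
  }
  meta <- NULL
  mfile <- file.path(path, "metadata.csv")
  if (file.exists(mfile)) {
    raw <- utils::read.csv(mfile, stringsAsFactors = FALSE)
    raw$subject_id <- as.character(raw$subject_id)
    absent <- setdiff(names(epochs), raw$subject_id)
    if (length(absent)) {
      warnf("subject(s) without metadata (scores set to NA): %s",
            paste(absent, collapse = ", "))
      raw <- rbind(raw, data.frame(subject_id = absent, bdi = NA, stai = NA,
                                   age = if ("age" %in% names(raw)) NA else NULL,
                                   gender = if ("gender" %in% names(raw)) NA else NULL))
    }
    meta <- subject_meta(raw$subject_id, raw$bdi, raw$stai,
                         age = raw$age %||% NA, gender = raw$gender %||% NA)
  }
  list(epochs = epochs, meta = meta)
}
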