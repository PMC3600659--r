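# EpochSet container: validated in-memory object plus a simple on-disk
# representation (raw little-endian float64 array + JSON sidecar with the
# metadata needed to reconstruct it).

#' Feedback-locked epoch set
#'
#' Container for multichannel, feedback-locked amplitude segments.
#'
#' @param amplitudes Numeric array `channel x sample x epoch`, in uV.
#' @param times Sample times in ms relative to feedback onset; strictly
#'   increasing, uniformly spaced at `1000/srate`.
#' @param channels Channel labels (length = first dim).
#' @param condition Condition label per epoch, `"PF"` or `"NF"`.
#' @param srate Sampling rate in Hz.
#' @return An object of class `prlt_epoch_set`.
#' @export
epoch_set <- function(amplitudes, times, channels, condition, srate) {
  stopifnot(is.array(amplitudes), length(dim(amplitudes)) == 3L)
  d <- dim(amplitudes)
  if (length(channels) != d[1]) stop("channel labels do not match array")
  if (length(times) != d[2]) stop("`times` does not match array")
  if (length(condition) != d[3]) stop("`condition` does not match array")
  if (!all(condition %in% c("PF", "NF"))) {
    stop("conditions must be 'PF' or 'NF'")
  }
  step <- 1000 / srate
  if (any(diff(times) <= 0) ||
      any(abs(diff(times) - step) > 1e-6)) {
    stop("`times` must be strictly increasing with spacing 1000/srate")
  }
  structure(list(amplitudes = amplitudes, times = times,
                 channels = channels,
                 condition = as.character(condition), srate = srate),
            class = "prlt_epoch_set")
}

#' @export
print.prlt_epoch_set <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf(
    "Epoch set: %d channels x %d samples x %d epochs (%s), %g Hz, %g..%g ms\n",
    length(x$channels), length(x$times), length(x$condition),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    x$srate, min(x$times), max(x$times)))
  invisible(x)
}

#' Subset an epoch set by epoch index
#'
#' @param x A `prlt_epoch_set`.
#' @param epochs Integer or logical index over epochs.
#' @return A `prlt_epoch_set` with the selected epochs.
#' @export
subset_epochs <- function(x, epochs) {
  stopifnot(inherits(x, "prlt_epoch_set"))
  epoch_set(x$amplitudes[, , epochs, drop = FALSE], x$times, x$channels,
            x$condition[epochs], x$srate)
}

#' Write / read an epoch set on disk
#'
#' The amplitudes are stored as little-endian float64 at `<stem>.dat` in
#' column-major `channel x sample x epoch` order; `<stem>.json` holds the
#' metadata (`channels`, `times_ms`, `srate_hz`, `condition`, `dim`).
#'
#' @param x A `prlt_epoch_set`.
#' @param stem Path stem (without extension).
#' @return `read_epoch_set()` returns a `prlt_epoch_set`.
#' @export
write_epoch_set <- function(x, stem) {
  stopifnot(inherits(x, "prlt_epoch_set"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(x$amplitudes), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(format = "prlterp-epochs-v1",
         dim = dim(x$amplitudes),
         channels = x$channels,
         times_ms = x$times,
         srate_hz = x$srate,
         condition = x$condition),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "prlterp-epochs-v1")) {
    stop("not a prlterp epoch container: ", stem)
  }
  n <- prod(meta$dim)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  amp <- readBin(con, "double", n = n, size = 8, endian = "little")
  epoch_set(array(amp, dim = meta$dim), times = meta$times_ms,
            channels = meta$channels, condition = meta$condition,
            srate = meta$srate_hz)
}
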