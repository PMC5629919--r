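#' Optode montage
#'
#' A montage describes the physical layout of an fNIRS measurement: the
#' source and detector optodes and the measurement channels, each channel
#' being one source-detector pair. The channel ordering convention is
#' source-major: all channels of the lowest-numbered source come first, in
#' ascending detector order, then the next source, and so on. Channel
#' indices used everywhere else in the package refer to this ordering.
#'
#' @param channels two-column matrix or data.frame of (source, detector)
#'   integer ID pairs, one row per channel. Rows may be given in any order;
#'   they are sorted into the canonical source-major order.
#' @param distance_cm source-detector separation in cm; a scalar (recycled)
#'   or one value per channel. Defaults to 3 cm, a standard adult
#'   scalp separation.
#' @param positions optional data.frame with columns `optode` ("S<i>" or
#'   "D<j>"), `x`, `y` giving 2-D layout coordinates in arbitrary units.
#' @return an object of class `"nirs_montage"` with elements `sources`,
#'   `detectors`, `channels` (integer matrix, source-major order),
#'   `distance_cm`, and `positions`.
#' @examples
#' m <- montage(rbind(c(2, 1), c(2, 2), c(3, 1), c(3, 2)))
#' n_channels(m)
#' channel_index(m, 2, 1)
#' @export
montage <- function(channels, distance_cm = 3.0, positions = NULL) {
  ch <- as.matrix(channels)
  if (ncol(ch) != 2L) stop("`channels` must have two columns (source, detector)")
  storage.mode(ch) <- "integer"
  if (anyNA(ch) || any(ch <= 0L)) stop("source/detector IDs must be positive integers")
  if (anyDuplicated(paste(ch[, 1L], ch[, 2L]))) stop("duplicate channel (source, detector) pairs")
  distance_cm <- rep_len(as.numeric(distance_cm), nrow(ch))
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0)) {
    stop("distance_cm must be positive and finite")
  }
  ord <- order(ch[, 1L], ch[, 2L])
  ch <- ch[ord, , drop = FALSE]
  distance_cm <- distance_cm[ord]
  dimnames(ch) <- list(NULL, c("source", "detector"))
  structure(
    list(
      sources = sort(unique(ch[, 1L])),
      detectors = sort(unique(ch[, 2L])),
      channels = ch,
      distance_cm = distance_cm,
      positions = positions
    ),
    class = "nirs_montage"
  )
}

#' @export
print.nirs_montage <- function(x, ...) {
  cat(sprintf(
    "fNIRS montage: %d sources, %d detectors, %d channels (source-major order)\n",
    length(x$sources), length(x$detectors), nrow(x$channels)
  ))
  cat(sprintf(
    "  source-detector distance: %s cm\n",
    paste(format(unique(x$distance_cm)), collapse = ", ")
  ))
  invisible(x)
}

#' Number of channels in a montage
#' @param montage a [montage()] object.
#' @export
n_channels <- function(montage) nrow(montage$channels)

#' Channel index of a source-detector pair
#'
#' Returns the position of a declared (source, detector) pair under the
#' canonical source-major channel ordering.
#'
#' @param montage a [montage()] object.
#' @param source,detector optode IDs.
#' @param base 1 for R-style indices (default) or 0 for stream/protocol
#'   file indices.
#' @return integer channel index.
#' @export
channel_index <- function(montage, source, detector, base = 1L) {
  hit <- which(montage$channels[, 1L] == source & montage$channels[, 2L] == detector)
  if (length(hit) != 1L) {
    stop(sprintf("no channel with source %d, detector %d in montage", source, detector))
  }
  as.integer(hit - 1L + base)
}

#' Read / write a montage file
#'
#' The montage file is a plain-text, whitespace-separated table. Lines
#' starting with `#` are comments. Channel lines have the form
#' `channel <source> <detector> <distance_cm>`; optional optode position
#' lines have the form `position <S_or_D><id> <x> <y>`.
#'
#' @param path file path.
#' @return `read_montage()` returns a [montage()]; `write_montage()`
#'   returns `path` invisibly.
#' @export
read_montage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ch <- list()
  pos <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t]+")[[1L]]
    if (tok[1L] == "channel") {
      if (length(tok) != 4L) stop(sprintf("%s:%d: malformed channel line", path, i))
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(v)) stop(sprintf("%s:%d: non-numeric channel fields", path, i))
      ch[[length(ch) + 1L]] <- v
    } else if (tok[1L] == "position") {
      if (length(tok) != 4L) stop(sprintf("%s:%d: malformed position line", path, i))
      xy <- suppressWarnings(as.numeric(tok[3:4]))
      if (anyNA(xy)) stop(sprintf("%s:%d: non-numeric position fields", path, i))
      pos[[length(pos) + 1L]] <- data.frame(optode = tok[2L], x = xy[1L], y = xy[2L])
    } else {
      stop(sprintf("%s:%d: unknown record type '%s'", path, i, tok[1L]))
    }
  }
  if (length(ch) == 0L) stop(sprintf("%s: no channel lines", path))
  chm <- do.call(rbind, ch)
  montage(chm[, 1:2, drop = FALSE],
    distance_cm = chm[, 3L],
    positions = if (length(pos)) do.call(rbind, pos) else NULL
  )
}

#' @rdname read_montage
#' @param montage a [montage()] object.
#' @export
write_montage <- function(montage, path) {
  lines <- c(
    "# rtnirs montage: channel <source> <detector> <distance_cm>",
    sprintf(
      "channel %d %d %s",
      montage$channels[, 1L], montage$channels[, 2L],
      format(montage$distance_cm, trim = TRUE, digits = 15)
    )
  )
  if (!is.null(montage$positions)) {
    lines <- c(lines, sprintf(
      "position %s %s %s",
      montage$positions$optode,
      format(montage$positions$x, trim = TRUE, digits = 15),
      format(montage$positions$y, trim = TRUE, digits = 15)
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
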