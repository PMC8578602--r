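# Closed 1-based intervals, stored as an integer matrix with columns
# start, end. All public coordinates in the package are 1-based and closed,
# following the UniProt convention.

#' Build an interval matrix
#'
#' @param starts,ends integer vectors of equal length (1-based, closed).
#' @return integer matrix with columns \code{start}, \code{end}.
#' @export
intervals <- function(starts = integer(), ends = integer()) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  stopifnot(length(starts) == length(ends))
  if (any(ends < starts)) stop("interval end before start")
  m <- cbind(start = starts, end = ends)
  m[order(m[, "start"]), , drop = FALSE]
}

iv_length <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  sum(iv[, "end"] - iv[, "start"] + 1L)
}

iv_positions <- function(iv) {
  if (nrow(iv) == 0L) return(integer())
  unlist(lapply(seq_len(nrow(iv)), function(k) iv[k, "start"]:iv[k, "end"]),
         use.names = FALSE)
}

iv_contains <- function(iv, pos) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv)))
    out <- out | (pos >= iv[k, "start"] & pos <= iv[k, "end"])
  out
}

# merge overlapping/adjacent-after-sorting intervals (closed arithmetic:
# [1,5],[6,9] merge only when touching, i.e. next start <= prev end + 1
# is NOT merged here unless overlapping; transfer/adjust use run-merging
# via positions instead where adjacency matters)
iv_merge_overlaps <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv[, "start"]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv[k, "start"] <= out[last, "end"] + 1L) {
      out[last, "end"] <- max(out[last, "end"], iv[k, "end"])
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  out
}

# intervals from a sorted vector of positions (maximal runs)
iv_from_positions <- function(pos) {
  pos <- sort(unique(as.integer(pos)))
  if (length(pos) == 0L) return(intervals())
  brk <- which(diff(pos) > 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))]
  intervals(starts, ends)
}

iv_validate <- function(iv, range = NULL, what = "intervals") {
  if (nrow(iv) == 0L) return(invisible(iv))
  if (any(iv[, "end"] < iv[, "start"]))
    stop(what, ": end before start")
  if (nrow(iv) > 1L) {
    o <- order(iv[, "start"])
    iv <- iv[o, , drop = FALSE]
    if (any(iv[-1, "start"] <= iv[-nrow(iv), "end"]))
      stop(what, ": intervals overlap")
  }
  if (!is.null(range)) {
    if (any(iv[, "start"] < range[1]) || any(iv[, "end"] > range[2]))
      stop(what, ": interval outside domain range [", range[1], ",",
           range[2], "]")
  }
  invisible(iv)
}
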