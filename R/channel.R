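# In-process two-party message transport with an append-only transcript.
# Both protocol roles run in one R process; a message "sent" by one role is
# queued for the other and recorded, so tests can audit exactly what crossed
# the wire. Messages are length-delimited raw byte strings.

PSI_ROLES <- c("researcher", "data_owner")

#' Create a two-party channel
#'
#' An ordered bidirectional transport between the roles `researcher` and
#' `data_owner`. Every message is appended to a transcript of
#' `(sender, label, bytes)` entries; per direction, messages are delivered in
#' send order. The transcript is what security-structure tests inspect: a
#' protocol's privacy claim is a claim about these bytes.
#'
#' @return An object of class `channel`.
#' @export
channel <- function() {
  env <- new.env(parent = emptyenv())
  env$transcript <- list()
  env$cursor <- c(researcher = 0L, data_owner = 0L) # last index read per receiver
  structure(env, class = "channel")
}

ch_send <- function(ch, sender, bytes, label = "") {
  stopifnot(inherits(ch, "channel"), sender %in% PSI_ROLES, is.raw(bytes))
  ch$transcript[[length(ch$transcript) + 1L]] <-
    list(sender = sender, label = label, bytes = bytes)
  invisible(ch)
}

ch_recv <- function(ch, receiver) {
  stopifnot(inherits(ch, "channel"), receiver %in% PSI_ROLES)
  other <- setdiff(PSI_ROLES, receiver)
  i <- ch$cursor[[receiver]]
  repeat {
    i <- i + 1L
    if (i > length(ch$transcript))
      stopf("protocol abort: %s expected a message at transcript position %d but none was sent",
            receiver, i)
    if (ch$transcript[[i]]$sender == other) break
  }
  ch$cursor[[receiver]] <- i
  ch$transcript[[i]]$bytes
}

#' Transcript of a channel
#'
#' @param ch a [channel()].
#' @return List of `(sender, label, bytes)` entries in send order.
#' @export
transcript <- function(ch) {
  stopifnot(inherits(ch, "channel"))
  ch$transcript
}

#' All transcript bytes as one raw vector (for audits)
#'
#' @param ch a [channel()].
#' @param sender optionally restrict to one sender role.
#' @return A raw vector.
#' @export
transcript_bytes <- function(ch, sender = NULL) {
  entries <- transcript(ch)
  if (!is.null(sender)) entries <- Filter(function(e) e$sender == sender, entries)
  if (length(entries) == 0) return(raw(0))
  do.call(c, lapply(entries, `[[`, "bytes"))
}

#' Dump a channel transcript to a log file
#'
#' One line per message: sender, label, byte count, hex payload.
#'
#' @param ch a [channel()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
dump_transcript <- function(ch, path) {
  lines <- vapply(transcript(ch), function(e) {
    sprintf("%s\t%s\t%d\t%s", e$sender, e$label, length(e$bytes),
            paste(as.character(e$bytes), collapse = ""))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("<channel> %d message(s), %d byte(s) total\n",
              length(x$transcript), length(transcript_bytes(x))))
  invisible(x)
}

# serialize a list of equal-width raw blobs as count || width || blobs
pack_blobs <- function(blobs, width) {
  stopifnot(all(lengths(blobs) == width))
  header <- writeBin(c(length(blobs), width), raw(), size = 4, endian = "big")
  c(header, do.call(c, c(blobs, list(raw(0)))))
}

unpack_blobs <- function(bytes) {
  if (length(bytes) < 8) stopf("protocol abort: malformed message (short header)")
  hdr <- readBin(bytes[1:8], integer(), n = 2, size = 4, endian = "big")
  n <- hdr[1]; width <- hdr[2]
  if (length(bytes) != 8 + n * width)
    stopf("protocol abort: malformed message (expected %d payload bytes, got %d)",
          n * width, length(bytes) - 8)
  lapply(seq_len(n), function(i) bytes[8 + (i - 1) * width + seq_len(width)])
}
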