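# Binary serialization of the dynamic graph state: a versioned container
# with magic bytes, a manifest of section lengths, fixed little-endian
# integer layout, and a Fletcher-style checksum over the payload.

.MAGIC <- charToRaw("BUFDBG01")
.FORMAT_VERSION <- 1L

.rawInt <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")
.rawDouble <- function(x) writeBin(as.numeric(x), raw(), size = 8L,
                                   endian = "little")
.rawBits <- function(bits) {
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  c(.rawInt(n), packBits(c(bits, rep(FALSE, pad)), type = "raw"))
}
.rawString <- function(s) {
  b <- charToRaw(s)
  c(.rawInt(length(b)), b)
}

# vectorised Fletcher-style checksum over the payload bytes
.checksum <- function(payload) {
  s <- as.numeric(as.integer(payload))   # doubles: no integer overflow
  a <- (1 + sum(s)) %% 65521
  b <- (length(s) + sum(cumsum(s))) %% 65521
  as.integer(a * 65536 + b)
}

# sequential reader over a raw vector
.reader <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- 1L
  env
}
.take <- function(rd, n) {
  if (rd$pos + n - 1L > length(rd$bytes))
    stop("state file truncated", call. = FALSE)
  out <- rd$bytes[seq.int(rd$pos, length.out = n)]
  rd$pos <- rd$pos + n
  out
}
.readInt <- function(rd) readBin(.take(rd, 4L), "integer", size = 4L,
                                 endian = "little")
.readDouble <- function(rd) readBin(.take(rd, 8L), "double", size = 8L,
                                    endian = "little")
.readBits <- function(rd) {
  n <- .readInt(rd)
  nbytes <- ceiling(n / 8)
  bits <- as.logical(rawToBits(.take(rd, nbytes)))
  bits[seq_len(n)]
}
.readString <- function(rd) rawToChar(.take(rd, .readInt(rd)))

#' Save a dynamic graph state to disk
#'
#' Writes the static index, both buffers, k and the flush threshold to a
#' versioned little-endian binary container ("BUFDBG01" magic, format
#' version, payload length manifest, checksum).  Round trips are bit-exact
#' on any platform.
#'
#' @param st a [BufBoss-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveState <- function(st, path) {
  stopifnot(is(st, "BufBoss"))
  idx <- st@index
  payload <- c(
    .rawInt(idx@k), .rawDouble(st@threshold),
    .rawInt(as.integer(st@useMark)),
    .rawInt(idx@nNodes), .rawInt(idx@nEdges),
    .rawString(paste(idx@ebwt, collapse = "")),
    .rawBits(idx@O@bits), .rawBits(idx@I@bits),
    .rawInt(length(st@haLabel)),
    .rawString(paste(st@haLabel, collapse = "\n")),
    .rawInt(st@haIn), .rawInt(st@haOut),
    .rawBits(st@bd))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.MAGIC, con)
  writeBin(c(.rawInt(.FORMAT_VERSION), .rawInt(length(payload)),
             .rawInt(.checksum(payload)), payload), con)
  invisible(path)
}

#' Load a dynamic graph state from disk
#'
#' Verifies the magic bytes, format version, manifest length and checksum,
#' then reconstructs the state; the rank/select directories are rebuilt
#' from the stored ebwt and degree bit vectors.
#'
#' @param path a file written by [saveState()].
#' @return A [BufBoss-class].
#' @export
loadState <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  rd <- .reader(bytes)
  if (!identical(.take(rd, 8L), .MAGIC))
    stop("not a saved graph state (bad magic bytes)", call. = FALSE)
  ver <- .readInt(rd)
  if (ver != .FORMAT_VERSION)
    stop("unsupported state format version ", ver, call. = FALSE)
  plen <- .readInt(rd)
  want <- .readInt(rd)
  payload <- .take(rd, plen)
  if (rd$pos != length(bytes) + 1L)
    stop("trailing bytes after payload", call. = FALSE)
  if (.checksum(payload) != want)
    stop("state file corrupted (checksum mismatch)", call. = FALSE)
  rd <- .reader(payload)
  k <- .readInt(rd)
  threshold <- .readDouble(rd)
  useMark <- as.logical(.readInt(rd))
  nNodes <- .readInt(rd)
  nEdges <- .readInt(rd)
  ebwt <- strsplit(.readString(rd), "", fixed = TRUE)[[1L]]
  obits <- .readBits(rd)
  ibits <- .readBits(rd)
  nha <- .readInt(rd)
  haLabel <- if (nha == 0L) { .readString(rd); character(0) }
             else strsplit(.readString(rd), "\n", fixed = TRUE)[[1L]]
  haIn <- readBin(.take(rd, 4L * nha), "integer", n = nha, size = 4L,
                  endian = "little")
  haOut <- readBin(.take(rd, 4L * nha), "integer", n = nha, size = 4L,
                   endian = "little")
  bd <- .readBits(rd)
  stopifnot(length(ebwt) == nEdges, length(haLabel) == nha)
  # rebuild the index through the canonical assembler
  outdeg <- diff(c(which(obits), length(obits) + 1L)) - 1L
  indeg <- diff(c(which(ibits), length(ibits) + 1L)) - 1L
  stopifnot(length(outdeg) == nNodes, sum(outdeg) == nEdges)
  outs <- split(ebwt, rep(seq_along(outdeg), outdeg))
  outsList <- rep(list(character(0)), nNodes)
  outsList[as.integer(names(outs))] <- outs
  idx <- .newBossIndex(k, outsList, indeg)
  st <- BufBoss(idx, threshold = threshold, useMark = useMark)
  st@haLabel <- haLabel
  st@haIn <- haIn
  st@haOut <- haOut
  st@bd <- bd
  if (useMark) st <- .refreshMark(st, seq_len(nNodes))
  validObject(st)
  st
}
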