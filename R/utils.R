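# Internal helpers shared across the index, buffers and merge code.

# Bit masks over the outgoing alphabet ACGT and incoming alphabet $ACGT.
.OUT_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.IN_BIT  <- c("$" = 1L, A = 2L, C = 4L, G = 8L, T = 16L)

.maskFromChars <- function(chars, bits) {
  if (length(chars) == 0L) return(0L)
  as.integer(sum(bits[unique(chars)]))
}

.charsFromMask <- function(mask, bits) names(bits)[bitwAnd(mask, bits) != 0L]

.popcount <- function(mask, bits) sum(bitwAnd(mask, bits) != 0L)

# 0/1 indicator string of a mask in the alphabet order of `bits`
.maskToString <- function(mask, bits)
  paste(as.integer(bitwAnd(mask, bits) != 0L), collapse = "")

.checkDna <- function(s, what = "sequence") {
  bad <- grepl("[^ACGT]", s)
  if (any(bad))
    stop(what, " contains characters outside A/C/G/T: ",
         paste(utils::head(s[bad], 3L), collapse = ", "), call. = FALSE)
  invisible(s)
}

# Left-pad labels with '$' to a fixed width.
.padLabels <- function(labels, width) {
  n <- nchar(labels)
  pad <- strrep("$", pmax(width - n, 0L))
  paste0(pad, labels)
}

# Colexicographic order of equal-width (padded) labels: radix order on the
# character columns taken right to left, in the C locale ('$' < 'A' < ... 'T').
.colexOrder <- function(padded, width) {
  if (length(padded) == 0L) return(integer(0))
  if (width == 0L) return(seq_along(padded))
  mat <- matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
                ncol = width, byrow = TRUE)
  keys <- lapply(seq.int(width, 1L), function(j) mat[, j])
  do.call(order, c(keys, list(method = "radix")))
}

# Navigation step counter: incremented by the elementary index operations
# (interval updates, out-edge rank computations, forward steps).  Used to
# verify the O(m) vs O(k*m) traversal cost contract of read queries.
.navEnv <- new.env(parent = emptyenv())
.navEnv$steps <- 0

.navTick <- function(n = 1L) .navEnv$steps <- .navEnv$steps + n

#' Navigation step instrumentation
#'
#' The index keeps a global counter of elementary navigation operations
#' (one backward-search interval update, one out-edge rank computation, or
#' one forward traversal step each count as one step).  `resetNavSteps()`
#' zeroes the counter, `navSteps()` reads it.  Used to verify that querying
#' all edgemers of an in-graph read of length m by graph traversal costs
#' O(m) steps, versus O(k*m) for independent searches.
#'
#' @return `navSteps()` returns the current count as a number.
#' @export
navSteps <- function() .navEnv$steps

#' @rdname navSteps
#' @export
resetNavSteps <- function() { .navEnv$steps <- 0; invisible(NULL) }
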