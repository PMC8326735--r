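# 2-bit k-mer codec: packing, reverse complement, canonicalization, and
# edgemer enumeration with invalid-character splitting.

# codes 0..3 for a character matrix of A/C/G/T
.charCodes <- function(mat) {
  codes <- match(mat, .DNA) - 1L
  matrix(codes, nrow = nrow(mat), ncol = ncol(mat))
}

# digits (codes, first char leftmost) -> (hi, lo) halves
.packDigits <- function(mat) {
  w <- ncol(mat)
  lo <- numeric(nrow(mat)); hi <- numeric(nrow(mat))
  for (j in seq_len(w)) {
    p <- w - j                      # exponent of this position
    if (p < 16L) lo <- lo + mat[, j] * 4^p
    else hi <- hi + mat[, j] * 4^(p - 16L)
  }
  list(hi = hi, lo = lo)
}

# (hi, lo, width) of one width group -> digit matrix
.unpackDigits <- function(hi, lo, w) {
  n <- length(hi)
  mat <- matrix(0L, nrow = n, ncol = max(w, 1L))
  for (j in seq_len(w)) {
    p <- w - j
    mat[, j] <- if (p < 16L) as.integer((lo %/% 4^p) %% 4)
                else as.integer((hi %/% 4^(p - 16L)) %% 4)
  }
  mat[, seq_len(w), drop = FALSE]
}

#' Encode DNA strings as packed k-mers
#'
#' Packs strings over A/C/G/T (lowercase accepted) into 2-bit-per-character
#' integers (A=0, C=1, G=2, T=3, first character most significant).  The
#' maximum length is 32 characters.
#'
#' @param s character vector of DNA strings (each of length 0..32).
#' @return A [PackedKmers-class] vector, one element per input string.
#' @examples
#' x <- encodeKmers(c("ACGT", "AAA"))
#' decodeKmers(x)
#' @export
encodeKmers <- function(s) {
  s <- toupper(as.character(s))
  .checkDna(s, "k-mer")
  w <- nchar(s)
  if (any(w > 32L)) stop("k-mers longer than 32 characters cannot be packed")
  hi <- numeric(length(s)); lo <- numeric(length(s))
  for (wd in unique(w)) {
    idx <- which(w == wd)
    if (wd == 0L) next
    mat <- matrix(unlist(strsplit(s[idx], "", fixed = TRUE), use.names = FALSE),
                  ncol = wd, byrow = TRUE)
    packed <- .packDigits(.charCodes(mat))
    hi[idx] <- packed$hi; lo[idx] <- packed$lo
  }
  new("PackedKmers", hi = hi, lo = lo, width = as.integer(w))
}

#' Decode packed k-mers back to strings
#' @param x a [PackedKmers-class] vector.
#' @return character vector of DNA strings.
#' @export
decodeKmers <- function(x) {
  stopifnot(is(x, "PackedKmers"))
  out <- character(length(x@width))
  for (wd in unique(x@width)) {
    idx <- which(x@width == wd)
    if (wd == 0L) { out[idx] <- ""; next }
    mat <- .unpackDigits(x@hi[idx], x@lo[idx], wd)
    chmat <- matrix(.DNA[mat + 1L], nrow = length(idx))
    out[idx] <- do.call(paste0, as.data.frame(chmat, stringsAsFactors = FALSE))
  }
  out
}

#' @describeIn PackedKmers number of k-mers in the vector.
#' @param x a \code{PackedKmers} vector.
#' @export
setMethod("length", "PackedKmers", function(x) length(x@width))

#' @describeIn PackedKmers decode to a character vector.
#' @export
setMethod("as.character", "PackedKmers", function(x) decodeKmers(x))

#' @describeIn PackedKmers subset the vector.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PackedKmers", function(x, i, j, ..., drop = TRUE)
  new("PackedKmers", hi = x@hi[i], lo = x@lo[i], width = x@width[i]))

#' Character length of each packed k-mer
#' @param x a [PackedKmers-class] vector.
#' @return integer vector of k-mer lengths.
#' @export
kmerLength <- function(x) {
  stopifnot(is(x, "PackedKmers"))
  x@width
}

#' @describeIn PackedKmers reverse complement, computed on the packed
#'   representation (complement each 2-bit code as 3 - code and reverse the
#'   character order).  An involution.
#' @export
setMethod("reverseComplement", "PackedKmers", function(x, ...) {
  hi <- x@hi; lo <- x@lo
  for (wd in unique(x@width)) {
    idx <- which(x@width == wd)
    if (wd == 0L) next
    mat <- .unpackDigits(x@hi[idx], x@lo[idx], wd)
    rcmat <- (3L - mat)[, seq.int(wd, 1L), drop = FALSE]
    packed <- .packDigits(rcmat)
    hi[idx] <- packed$hi; lo[idx] <- packed$lo
  }
  new("PackedKmers", hi = hi, lo = lo, width = x@width)
})

#' Canonical form of packed k-mers
#'
#' The canonical form of a k-mer is the smaller of the k-mer and its reverse
#' complement.  The index itself never canonicalizes (both strands are
#' indexed by also processing reverse-complemented sequences); this helper
#' exists for reporting distinct-canonical-edgemer counts.
#'
#' @param x a [PackedKmers-class] vector.
#' @return A [PackedKmers-class] vector of canonical k-mers.
#' @export
canonicalKmers <- function(x) {
  rc <- reverseComplement(x)
  # compare (hi, lo) numerically: equal widths compare like strings
  takeRc <- rc@hi < x@hi | (rc@hi == x@hi & rc@lo < x@lo)
  new("PackedKmers",
      hi = ifelse(takeRc, rc@hi, x@hi),
      lo = ifelse(takeRc, rc@lo, x@lo),
      width = x@width)
}

# string-level reverse complement (used for whole input sequences)
.rcString <- function(s) {
  comp <- chartr("ACGT", "TGCA", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Split sequences at non-DNA characters
#'
#' Returns the maximal runs of A/C/G/T characters of a sequence, in order.
#' Any other character (N, IUPAC ambiguity codes, gaps, ...) acts as a split
#' point.  Lowercase input is upper-cased first.
#'
#' @param seq character vector of sequences.
#' @return For a single sequence, a character vector of pieces (possibly
#'   empty); for several sequences, a list of such vectors.
#' @examples
#' splitOnInvalid("ACGNTA")   # "ACG" "TA"
#' @export
splitOnInvalid <- function(seq) {
  seq <- toupper(as.character(seq))
  pieces <- regmatches(seq, gregexpr("[ACGT]+", seq))
  if (length(seq) == 1L) pieces[[1L]] else pieces
}

#' Enumerate the distinct edgemers of a set of sequences
#'
#' Lists all distinct length-k substrings of the valid (ACGT-only) pieces of
#' the input sequences.  With \code{addRc = TRUE} the reverse complement of
#' every sequence is processed as well, so that both strands are indexed.
#'
#' @param seqs character vector (or anything coercible with
#'   \code{as.character}, e.g. a \code{DNAStringSet}) of input sequences.
#' @param k integer edgemer length, 2..32.
#' @param addRc also process reverse complements (default FALSE).
#' @return A [PackedKmers-class] vector of the distinct edgemers.
#' @examples
#' decodeKmers(enumerateEdgemers("ACGTA", k = 4))
#' @export
enumerateEdgemers <- function(seqs, k, addRc = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 32L) stop("k must be in 2..32")
  seqs <- as.character(seqs)
  pieces <- unlist(splitOnInvalid(seqs), use.names = FALSE)
  if (is.null(pieces)) pieces <- character(0)
  if (isTRUE(addRc)) pieces <- c(pieces, .rcString(pieces))
  pieces <- pieces[nchar(pieces) >= k]
  mers <- unlist(lapply(pieces, function(p) {
    n <- nchar(p)
    substring(p, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  if (is.null(mers)) mers <- character(0)
  encodeKmers(unique(mers))
}
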