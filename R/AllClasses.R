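#' @import methods
NULL

# DNA alphabet used throughout; the incoming-edge alphabet additionally has
# '$' (sorting before 'A' in every colexicographic comparison).
.DNA <- c("A", "C", "G", "T")
.DNA_IN <- c("$", "A", "C", "G", "T")

#' PackedKmers: 2-bit packed DNA k-mers
#'
#' A vector-like container of DNA k-mers of up to 32 characters, each packed
#' 2 bits per character (A=0, C=1, G=2, T=3) with the first character in the
#' most significant position.  Because R has no native 64-bit integer, the
#' packed value is held in two exact 32-bit halves stored as doubles:
#' \code{hi} packs all but the last 16 characters, \code{lo} the last (up to)
#' 16.  The conceptual packed integer is \code{hi * 4^16 + lo}.
#'
#' @slot hi numeric, high halves of the packed values.
#' @slot lo numeric, low halves of the packed values.
#' @slot width integer, number of characters of each k-mer (0..32).
#'
#' @seealso [encodeKmers()], [decodeKmers()], [canonicalKmers()]
#' @exportClass PackedKmers
setClass("PackedKmers",
  representation(hi = "numeric", lo = "numeric", width = "integer"))

setValidity("PackedKmers", function(object) {
  n <- length(object@width)
  if (length(object@hi) != n || length(object@lo) != n)
    return("hi, lo and width must have equal length")
  if (n == 0L) return(TRUE)
  if (any(object@width < 0L | object@width > 32L))
    return("k-mer length must be in 0..32")
  if (any(object@hi != floor(object@hi)) || any(object@lo != floor(object@lo)))
    return("packed values must be integral")
  if (any(object@hi < 0) || any(object@lo < 0))
    return("packed values must be non-negative")
  wlo <- pmin(object@width, 16L)
  whi <- pmax(object@width - 16L, 0L)
  if (any(object@lo >= 4^wlo) || any(object@hi >= 4^whi))
    return("packed value uses more than 2*width bits")
  TRUE
})

#' Static bit vector with rank/select support
#'
#' Plain-prefix-sum rank directory and positional select arrays over a static
#' 0/1 sequence.  rank1(i) counts ones in the first i positions; select1(j)
#' returns the position of the j-th one (1-based).
#'
#' @slot bits logical vector.
#' @slot rank integer, cumulative count of ones.
#' @slot pos1,pos0 integer, positions of the ones / zeros.
#' @exportClass RankSelectBits
setClass("RankSelectBits",
  representation(bits = "logical", rank = "integer",
                 pos1 = "integer", pos0 = "integer"))

setValidity("RankSelectBits", function(object) {
  n <- length(object@bits)
  if (length(object@rank) != n) return("rank directory length mismatch")
  if (n > 0L && !identical(object@rank, cumsum(object@bits)))
    return("rank directory inconsistent with bits")
  if (!identical(object@pos1, which(object@bits)))
    return("pos1 inconsistent with bits")
  if (!identical(object@pos0, which(!object@bits)))
    return("pos0 inconsistent with bits")
  TRUE
})

#' Construct a RankSelectBits vector
#' @param bits logical (or 0/1) vector.
#' @return A [RankSelectBits-class] object.
#' @export
RankSelectBits <- function(bits) {
  bits <- as.logical(bits)
  stopifnot(!anyNA(bits))
  new("RankSelectBits", bits = bits,
      rank = as.integer(cumsum(bits)),
      pos1 = which(bits), pos0 = which(!bits))
}

#' The static Wheeler-graph (BOSS) index
#'
#' A succinct representation of an edge-centric de Bruijn graph with edgemer
#' length \code{k}, including the dummy-node tree rooted at the empty string.
#' Nodes are identified by their 1-based colexicographic rank among the
#' $-left-padded node labels (with $ < A < C < G < T); edges by the
#' colexicographic rank of their (padded) edgemer labels.
#'
#' @slot k integer edgemer length (nodemers have length k-1).
#' @slot ebwt character vector of single-character edge labels, grouped by
#'   origin node in colexicographic order, label-sorted within each node.
#' @slot O,I [RankSelectBits-class]: out/indegree unary encodings, degree d
#'   encoded as 1 followed by d zeros, nodes in colexicographic order.
#' @slot cTable named integer: for each character, the number of edge labels that
#'   are strictly smaller (prefix sums of ebwt character counts).
#' @slot occ named list of integer vectors: positions of each character in
#'   ebwt (positional select/rank support).
#' @slot nNodes,nEdges integer counts.
#' @exportClass BossIndex
setClass("BossIndex",
  representation(k = "integer", ebwt = "character",
                 O = "RankSelectBits", I = "RankSelectBits",
                 cTable = "integer", occ = "list",
                 nNodes = "integer", nEdges = "integer"))

setValidity("BossIndex", function(object) {
  if (object@k < 2L || object@k > 32L) return("k must be in 2..32")
  n <- object@nNodes; m <- object@nEdges
  if (length(object@ebwt) != m) return("ebwt length != nEdges")
  if (sum(object@O@bits) != n || sum(object@I@bits) != n)
    return("number of ones in O and I must equal nNodes")
  if (sum(!object@O@bits) != m || sum(!object@I@bits) != m)
    return("number of zeros in O and I must equal nEdges")
  if (n < 1L) return("the empty-string root must always be present")
  # indegree of the root (rank 1) is 0; all other nodes have indegree >= 1
  ind <- diff(c(object@I@pos1, length(object@I@bits) + 1L)) - 1L
  if (ind[1L] != 0L) return("root node must have indegree 0")
  if (n > 1L && any(ind[-1L] < 1L))
    return("every non-root node must have indegree >= 1")
  cnt <- vapply(.DNA, function(ch) sum(object@ebwt == ch), 0L)
  if (!identical(unname(object@cTable), unname(cumsum(c(0L, cnt))[1:4])))
    return("C is not the prefix sum of ebwt character counts")
  for (ch in .DNA)
    if (!identical(object@occ[[ch]], which(object@ebwt == ch)))
      return("occ positions inconsistent with ebwt")
  TRUE
})

#' A dynamic buffered de Bruijn graph
#'
#' Couples a static [BossIndex-class] with an addition buffer (an associative
#' map from nodemer labels to incoming/outgoing label bitsets) and a deletion
#' buffer (one bit per colexicographic edge rank).  Queries and traversal see
#' the modified graph with edge set (E u A) \\ D.  Bitsets are stored as
#' integer masks: outgoing over ACGT (A=1, C=2, G=4, T=8), incoming over
#' $ACGT ($=1, A=2, C=4, G=8, T=16).
#'
#' @slot index the static [BossIndex-class].
#' @slot haLabel character, addition-buffer keys (nodemer labels).
#' @slot haIn,haOut integer bit masks parallel to \code{haLabel}.
#' @slot bd logical, deletion flags indexed by edge colexicographic rank.
#' @slot threshold numeric flush threshold in [0,1].
#' @slot useMark logical, whether the node-mark accelerator is maintained.
#' @slot mark logical, per-node flag: label is a buffer key or an incident
#'   edge is marked deleted (length 0 when \code{useMark} is FALSE).
#' @exportClass BufBoss
setClass("BufBoss",
  representation(index = "BossIndex", haLabel = "character",
                 haIn = "integer", haOut = "integer",
                 bd = "logical", threshold = "numeric",
                 useMark = "logical", mark = "logical"))

setValidity("BufBoss", function(object) {
  nh <- length(object@haLabel)
  if (length(object@haIn) != nh || length(object@haOut) != nh)
    return("addition-buffer slots must have equal length")
  if (nh > 0L && any(object@haIn == 0L & object@haOut == 0L))
    return("every addition-buffer entry must have at least one bit set")
  if (anyDuplicated(object@haLabel)) return("duplicate addition-buffer keys")
  if (length(object@bd) != object@index@nEdges)
    return("deletion buffer length != nEdges")
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must be in [0,1]")
  if (object@useMark && length(object@mark) != object@index@nNodes)
    return("mark vector length != nNodes")
  TRUE
})

#' Node token: a node of the modified graph
#'
#' A node of the buffered graph is represented by its label together with its
#' colexicographic rank in the static index (NA when absent) and its
#' addition-buffer entry (NA masks when the label is not a buffer key).
#'
#' @slot label nodemer label.
#' @slot rank integer node rank or NA.
#' @slot inMask,outMask integer buffer masks or NA.
#' @exportClass NodeToken
setClass("NodeToken",
  representation(label = "character", rank = "integer",
                 inMask = "integer", outMask = "integer"))

setMethod("show", "PackedKmers", function(object) {
  n <- length(object@width)
  cat("PackedKmers of length", n, "\n")
  if (n > 0L) {
    shown <- utils::head(decodeKmers(object), 6L)
    cat(" ", paste(shown, collapse = " "),
        if (n > 6L) "..." else "", "\n")
  }
})

setMethod("show", "BossIndex", function(object) {
  cat("BossIndex: edgemer length k =", object@k, "\n")
  cat("  ", object@nNodes, "nodes,", object@nEdges,
      "edges (incl. dummy tree)\n")
})

setMethod("show", "BufBoss", function(object) {
  cat("BufBoss dynamic de Bruijn graph (k =", object@index@k, ")\n")
  cat("  static index:", object@index@nNodes, "nodes,",
      object@index@nEdges, "edges\n")
  cat("  addition buffer:", length(object@haLabel), "nodemer entries\n")
  cat("  deletion buffer:", sum(object@bd), "marked edges\n")
  cat("  flush threshold:", object@threshold,
      if (object@useMark) " (mark accelerator on)" else "", "\n")
})

setMethod("show", "NodeToken", function(object) {
  cat("NodeToken '", object@label, "' rank=",
      ifelse(is.na(object@rank), "absent", object@rank),
      " buffered=", !is.na(object@inMask), "\n", sep = "")
})
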