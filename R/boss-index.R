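# Navigation operations on the static Wheeler-graph index.
#
# All ranks are 1-based.  Node order is the colexicographic order of the
# $-left-padded node labels; edge rank colex(e) is the rank of the (padded)
# edgemer label, equivalently: sort by last character, then by origin node.
# The ebwt position of an edge and its colex rank are related by the classic
# last-to-first mapping through the C table and per-character ebwt rank.

# --- rank/select primitives -------------------------------------------------

bitRank1 <- function(x, i) if (i < 1L) 0L else x@rank[i]
bitRank0 <- function(x, i) if (i < 1L) 0L else i - x@rank[i]
bitSelect1 <- function(x, j) x@pos1[j]
bitSelect0 <- function(x, j) x@pos0[j]

# number of occurrences of character ch in ebwt[1..i]
.ebwtRank <- function(index, ch, i) {
  if (i < 1L) return(0L)
  findInterval(i, index@occ[[ch]])
}

# ebwt positions (out-edges) of nodes lo..hi, as c(first, last); first > last
# when the span has no edges
.outSpan <- function(index, lo, hi) {
  first <- index@O@pos1[lo] - lo + 1L
  last <- if (hi < index@nNodes) index@O@pos1[hi + 1L] - (hi + 1L)
          else index@nEdges
  c(first, last)
}

# destination node of the edge with colexicographic rank r
.edgeDest <- function(index, r) {
  p <- index@I@pos0[r]
  p - r
}

# origin node of the edge at ebwt position p
.edgeOrigin <- function(index, p) {
  q <- index@O@pos0[p]
  q - p
}

.emptyInterval <- c(1L, 0L)
.isEmptyInterval <- function(iv) iv[1L] > iv[2L]

# --- interval search --------------------------------------------------------

#' Follow same-labeled edges out of a node interval
#'
#' Given a closed interval of node ranks, returns the (contiguous, possibly
#' empty) interval of destination nodes of all edges with label \code{ch}
#' leaving the interval.  This is the elementary step of backward search on
#' the Wheeler graph.
#'
#' @param index a [BossIndex-class].
#' @param iv integer vector \code{c(lo, hi)}; \code{lo > hi} means empty.
#' @param ch a single character in A/C/G/T.
#' @return integer vector \code{c(lo, hi)} of destination node ranks.
#' @export
updateInterval <- function(index, iv, ch) {
  .navTick()
  if (.isEmptyInterval(iv)) return(.emptyInterval)
  span <- .outSpan(index, iv[1L], iv[2L])
  if (span[1L] > span[2L]) return(.emptyInterval)
  r1 <- index@cTable[[ch]] + .ebwtRank(index, ch, span[1L] - 1L) + 1L
  r2 <- index@cTable[[ch]] + .ebwtRank(index, ch, span[2L])
  if (r1 > r2) return(.emptyInterval)
  c(.edgeDest(index, r1), .edgeDest(index, r2))
}

#' Locate a node by its label
#'
#' Returns the colexicographic rank of the node with the given label, or NA
#' if absent.  A full-length label (k-1 characters) is searched from the
#' interval of all nodes; shorter (dummy-prefix) labels are searched from the
#' root, following the dummy tree.  The empty string locates the root
#' (rank 1).
#'
#' @param index a [BossIndex-class].
#' @param label string over A/C/G/T, at most k-1 characters.
#' @return integer node rank, or \code{NA_integer_}.
#' @export
nodeSearch <- function(index, label) {
  label <- toupper(label)
  .checkDna(label, "node label")
  n <- nchar(label)
  if (n > index@k - 1L) stop("node label longer than k-1")
  if (n == 0L) return(1L)
  iv <- if (n == index@k - 1L) c(1L, index@nNodes) else c(1L, 1L)
  chars <- strsplit(label, "", fixed = TRUE)[[1L]]
  for (ch in chars) {
    iv <- updateInterval(index, iv, ch)
    if (.isEmptyInterval(iv)) return(NA_integer_)
  }
  stopifnot(iv[1L] == iv[2L])
  iv[1L]
}

#' Locate an edge by its edgemer label
#'
#' @param index a [BossIndex-class].
#' @param e an edgemer: a length-k string or a single [PackedKmers-class].
#' @return integer edge colexicographic rank, or \code{NA_integer_}.
#' @export
edgeSearch <- function(index, e) {
  if (is(e, "PackedKmers")) e <- decodeKmers(e)
  if (nchar(e) != index@k) stop("edgemer must have length k")
  v <- nodeSearch(index, substr(e, 1L, index@k - 1L))
  if (is.na(v)) return(NA_integer_)
  outEdgeRank(index, v, substr(e, index@k, index@k))
}

# --- per-node operations ----------------------------------------------------

#' Outgoing edge labels of a node
#' @param index a [BossIndex-class].
#' @param v integer node rank.
#' @return character vector of single-character labels, sorted.
#' @export
outLabels <- function(index, v) {
  .checkRank(index, v)
  span <- .outSpan(index, v, v)
  if (span[1L] > span[2L]) character(0) else index@ebwt[span[1L]:span[2L]]
}

#' Incoming edge label of a node
#'
#' All incoming edges of a Wheeler-graph node carry the same label (the last
#' character of the node label); returns it, or NA for the root.
#' @inheritParams outLabels
#' @return single character, or \code{NA_character_}.
#' @export
inLabel <- function(index, v) {
  .checkRank(index, v)
  iv <- inEdgeInterval(index, v)
  if (.isEmptyInterval(iv)) return(NA_character_)
  .edgeChar(index, iv[1L])
}

# character of the edge with colexicographic rank r
.edgeChar <- function(index, r) .DNA[findInterval(r - 0.5, index@cTable)]

#' Interval of incoming edge ranks of a node
#' @inheritParams outLabels
#' @return integer \code{c(lo, hi)} of edge colexicographic ranks; empty
#'   (lo > hi) for indegree 0.
#' @export
inEdgeInterval <- function(index, v) {
  .checkRank(index, v)
  lo <- index@I@pos1[v] - v + 1L
  hi <- if (v < index@nNodes) index@I@pos1[v + 1L] - (v + 1L)
        else index@nEdges
  if (lo > hi) .emptyInterval else c(lo, hi)
}

#' Colexicographic rank of an outgoing edge
#' @inheritParams outLabels
#' @param ch single character in A/C/G/T.
#' @return integer edge rank, or \code{NA_integer_} if the node has no
#'   outgoing edge with that label.
#' @export
outEdgeRank <- function(index, v, ch) {
  .checkRank(index, v)
  .navTick()
  span <- .outSpan(index, v, v)
  if (span[1L] > span[2L]) return(NA_integer_)
  hit <- span[1L]:span[2L]
  p <- hit[index@ebwt[hit] == ch]
  if (length(p) == 0L) return(NA_integer_)
  index@cTable[[ch]] + .ebwtRank(index, ch, p[1L])
}

#' Forward traversal: destination of an edge
#'
#' The edge may be given either by its colexicographic rank, or by its origin
#' node rank and single-character label.
#'
#' @param index a [BossIndex-class].
#' @param v integer origin node rank (with \code{ch}).
#' @param ch single character edge label (with \code{v}).
#' @param edge integer edge colexicographic rank (alternative to v/ch).
#' @return integer destination node rank.
#' @export
bossForward <- function(index, v = NULL, ch = NULL, edge = NULL) {
  if (is.null(edge)) {
    edge <- outEdgeRank(index, v, ch)
    if (is.na(edge)) stop("no outgoing edge labeled '", ch, "' from node ", v)
  } else {
    .navTick()
    if (edge < 1L || edge > index@nEdges) stop("edge rank out of range")
  }
  .edgeDest(index, edge)
}

#' Backward traversal: a predecessor of a node
#'
#' Returns the predecessor with the smallest colexicographic rank (the
#' Wheeler order allows several; the smallest is chosen for determinism), or
#' NA when the node has indegree 0.
#' @inheritParams outLabels
#' @return integer node rank or \code{NA_integer_}.
#' @export
bossBackward <- function(index, v) {
  iv <- inEdgeInterval(index, v)
  if (.isEmptyInterval(iv)) return(NA_integer_)
  .navTick()
  r <- iv[1L]
  ch <- .edgeChar(index, r)
  p <- index@occ[[ch]][r - index@cTable[[ch]]]
  .edgeOrigin(index, p)
}

#' Label of a node
#'
#' Reconstructs the node label by walking backward up to k-1 steps and
#' collecting the incoming edge labels.  Dummy nodes give labels shorter than
#' k-1; the root gives the empty string.
#' @inheritParams outLabels
#' @return character node label (without $-padding).
#' @export
nodeLabel <- function(index, v) {
  .checkRank(index, v)
  chars <- character(0)
  for (step in seq_len(index@k - 1L)) {
    ch <- inLabel(index, v)
    if (is.na(ch)) break
    chars <- c(chars, ch)
    v <- bossBackward(index, v)
  }
  paste(rev(chars), collapse = "")
}

.checkRank <- function(index, v) {
  if (length(v) != 1L || is.na(v) || v < 1L || v > index@nNodes)
    stop("node rank out of range [1, ", index@nNodes, "]")
  invisible(v)
}

# --- degrees and dummy detection -------------------------------------------

#' Node degrees in the static index
#' @inheritParams outLabels
#' @return integer degree.
#' @export
outDegree <- function(index, v) {
  .checkRank(index, v)
  span <- .outSpan(index, v, v)
  max(span[2L] - span[1L] + 1L, 0L)
}

#' @rdname outDegree
#' @export
inDegree <- function(index, v) {
  iv <- inEdgeInterval(index, v)
  max(iv[2L] - iv[1L] + 1L, 0L)
}

# Flag the dummy nodes (labels shorter than k-1): breadth-first search from
# the root, which reaches exactly the dummy tree in at most k-2 steps.
.dummyFlags <- function(index) {
  flags <- logical(index@nNodes)
  flags[1L] <- TRUE
  frontier <- 1L
  depth <- 0L
  while (length(frontier) > 0L && depth < index@k - 2L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (ch in outLabels(index, v)) {
        u <- .edgeDest(index, outEdgeRank(index, v, ch))
        flags[u] <- TRUE
        nxt <- c(nxt, u)
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  flags
}

#' Index size accessors
#' @param index a [BossIndex-class] (or [BufBoss-class], whose static index
#'   is consulted).
#' @return integer count.
#' @export
nNodes <- function(index) .asIndex(index)@nNodes

#' @rdname nNodes
#' @export
nEdges <- function(index) .asIndex(index)@nEdges

#' @rdname nNodes
#' @export
edgemerLength <- function(index) .asIndex(index)@k

.asIndex <- function(x) {
  if (is(x, "BufBoss")) x@index
  else if (is(x, "BossIndex")) x
  else stop("expected a BossIndex or BufBoss")
}

#' Degree sequences in colexicographic node order
#' @param index a [BossIndex-class].
#' @return integer vector of length \code{nNodes(index)}.
#' @export
outDegrees <- function(index) {
  diff(c(index@O@pos1, length(index@O@bits) + 1L)) - 1L
}

#' @rdname outDegrees
#' @export
inDegrees <- function(index) {
  diff(c(index@I@pos1, length(index@I@bits) + 1L)) - 1L
}

#' Compare two indexes for bit-identity
#'
#' Two indexes are identical when k, the ebwt string and the unary degree
#' bit vectors O and I coincide (these determine the graph completely).
#' @param a,b [BossIndex-class] objects.
#' @return logical.
#' @export
bossIdentical <- function(a, b) {
  identical(a@k, b@k) && identical(a@ebwt, b@ebwt) &&
    identical(a@O@bits, b@O@bits) && identical(a@I@bits, b@I@bits)
}
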