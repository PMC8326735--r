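# Dynamic layer: addition buffer (nodemer -> in/out label bitsets), deletion
# buffer (one bit per edge colexicographic rank), node tokens, and queries on
# the modified graph with edge set (E u A) \ D.
#
# Synchronization invariants maintained by every operation:
#   A and D are disjoint, A and E are disjoint, D is a subset of E.

#' Create a dynamic buffered graph over a static index
#'
#' @param index a [BossIndex-class] (e.g. from [buildIndex()]).
#' @param threshold flush threshold in [0,1]: the buffers are flushed by
#'   [flushIfNeeded()] when the number of addition-buffer keys exceeds
#'   \code{threshold * nEdges(index)}.  Default 0.025.
#' @param useMark maintain the optional per-node mark accelerator (a bit per
#'   node, set when the node label is a buffer key or an incident edge is
#'   marked deleted).  Query results never depend on it.
#' @return A [BufBoss-class] object with empty buffers.
#' @examples
#' st <- BufBoss(buildIndex(c("ACGT", "CGTA"), 4))
#' edgemerPresent(st, "ACGT")
#' @export
BufBoss <- function(index, threshold = 0.025, useMark = FALSE) {
  stopifnot(is(index, "BossIndex"))
  new("BufBoss", index = index, haLabel = character(0),
      haIn = integer(0), haOut = integer(0),
      bd = logical(index@nEdges), threshold = as.numeric(threshold),
      useMark = isTRUE(useMark),
      mark = if (isTRUE(useMark)) logical(index@nNodes) else logical(0))
}

# --- addition-buffer primitives --------------------------------------------

.haGet <- function(st, label) match(label, st@haLabel)

# set (or clear) a bit of an entry, creating/dropping the entry as needed
.haSetBit <- function(st, label, side = c("in", "out"), ch, on = TRUE) {
  side <- match.arg(side)
  bit <- if (side == "in") .IN_BIT[[ch]] else .OUT_BIT[[ch]]
  i <- .haGet(st, label)
  if (is.na(i)) {
    if (!on) return(st)
    st@haLabel <- c(st@haLabel, label)
    st@haIn <- c(st@haIn, if (side == "in") bit else 0L)
    st@haOut <- c(st@haOut, if (side == "out") bit else 0L)
    return(st)
  }
  if (side == "in")
    st@haIn[i] <- if (on) bitwOr(st@haIn[i], bit)
                  else bitwAnd(st@haIn[i], bitwNot(bit))
  else
    st@haOut[i] <- if (on) bitwOr(st@haOut[i], bit)
                   else bitwAnd(st@haOut[i], bitwNot(bit))
  if (st@haIn[i] == 0L && st@haOut[i] == 0L) {
    st@haLabel <- st@haLabel[-i]
    st@haIn <- st@haIn[-i]
    st@haOut <- st@haOut[-i]
  }
  st
}

# is edgemer e fully recorded in the addition buffer?
.haHasEdgemer <- function(st, pre, lastc, suf, firstc) {
  i <- .haGet(st, pre); j <- .haGet(st, suf)
  !is.na(i) && !is.na(j) &&
    bitwAnd(st@haOut[i], .OUT_BIT[[lastc]]) != 0L &&
    bitwAnd(st@haIn[j], .IN_BIT[[firstc]]) != 0L
}

#' Read an addition-buffer entry
#'
#' Returns the stored label bitsets for a nodemer key, both as masks and as
#' 0/1 indicator strings (incoming over the alphabet $ACGT, outgoing over
#' ACGT), or NULL when the label is not a key.
#'
#' @param st a [BufBoss-class].
#' @param label nodemer label.
#' @return list with elements \code{inMask}, \code{outMask}, \code{inBits},
#'   \code{outBits}, or NULL.
#' @export
haEntry <- function(st, label) {
  i <- .haGet(st, toupper(label))
  if (is.na(i)) return(NULL)
  list(inMask = st@haIn[i], outMask = st@haOut[i],
       inBits = .maskToString(st@haIn[i], .IN_BIT),
       outBits = .maskToString(st@haOut[i], .OUT_BIT))
}

#' Number of addition-buffer keys
#' @param st a [BufBoss-class].
#' @return integer.
#' @export
haSize <- function(st) length(st@haLabel)

# --- mark accelerator -------------------------------------------------------

# recompute the mark bit of the given node ranks from first principles
.refreshMark <- function(st, ranks) {
  if (!st@useMark) return(st)
  ranks <- unique(ranks[!is.na(ranks)])
  for (v in ranks) {
    lab <- nodeLabel(st@index, v)
    m <- !is.na(.haGet(st, lab))
    if (!m && any(st@bd)) {
      iv <- inEdgeInterval(st@index, v)
      if (!.isEmptyInterval(iv) && any(st@bd[iv[1L]:iv[2L]])) m <- TRUE
      if (!m) for (ch in outLabels(st@index, v))
        if (st@bd[outEdgeRank(st@index, v, ch)]) { m <- TRUE; break }
    }
    st@mark[v] <- m
  }
  st
}

# ranks (possibly NA) of the two endpoint nodemers of an edgemer
.edgemerEndpointRanks <- function(st, pre, suf) {
  c(nodeSearch(st@index, pre), nodeSearch(st@index, suf))
}

# --- updates ----------------------------------------------------------------

.splitEdgemer <- function(st, e) {
  if (is(e, "PackedKmers")) e <- decodeKmers(e)
  e <- toupper(e)
  k <- st@index@k
  if (any(nchar(e) != k)) stop("edgemers must have length k = ", k)
  .checkDna(e, "edgemer")
  list(e = e,
       pre = substr(e, 1L, k - 1L), lastc = substr(e, k, k),
       suf = substr(e, 2L, k), firstc = substr(e, 1L, 1L))
}

#' Buffer edgemer additions
#'
#' Each edgemer is split into its prefix and suffix nodemers; the prefix's
#' outgoing bit (last character) and the suffix's incoming bit (first
#' character) are set in the addition buffer.  An edgemer already present in
#' the static index is a no-op, unless it is marked deleted, in which case
#' the deletion mark is cleared instead (the buffers are kept synchronized:
#' the addition set never intersects the index or the deletion set).
#'
#' @param st a [BufBoss-class].
#' @param e edgemers: character vector or [PackedKmers-class], each of
#'   length k.
#' @return The updated [BufBoss-class].
#' @export
addEdgemers <- function(st, e) {
  p <- .splitEdgemer(st, e)
  for (i in seq_along(p$e)) {
    r <- edgeSearch(st@index, p$e[i])
    if (!is.na(r)) {
      if (st@bd[r]) {
        st@bd[r] <- FALSE
        st <- .refreshMark(st, .edgemerEndpointRanks(st, p$pre[i], p$suf[i]))
      }
      next                        # already in the index: nothing to buffer
    }
    st <- .haSetBit(st, p$pre[i], "out", p$lastc[i])
    st <- .haSetBit(st, p$suf[i], "in", p$firstc[i])
    st <- .refreshMark(st, .edgemerEndpointRanks(st, p$pre[i], p$suf[i]))
  }
  validObject(st)
  st
}

#' Buffer edgemer deletions
#'
#' An edgemer recorded in the addition buffer has its bits cleared there
#' (entries left without any bit are dropped); an edgemer of the static
#' index is marked in the deletion bit vector; deleting an absent edgemer is
#' a warning-level no-op.
#'
#' @inheritParams addEdgemers
#' @return The updated [BufBoss-class].
#' @export
deleteEdgemers <- function(st, e) {
  p <- .splitEdgemer(st, e)
  for (i in seq_along(p$e)) {
    if (.haHasEdgemer(st, p$pre[i], p$lastc[i], p$suf[i], p$firstc[i])) {
      st <- .haSetBit(st, p$pre[i], "out", p$lastc[i], on = FALSE)
      st <- .haSetBit(st, p$suf[i], "in", p$firstc[i], on = FALSE)
      st <- .refreshMark(st, .edgemerEndpointRanks(st, p$pre[i], p$suf[i]))
      next
    }
    r <- edgeSearch(st@index, p$e[i])
    if (!is.na(r)) {
      st@bd[r] <- TRUE
      st <- .refreshMark(st, .edgemerEndpointRanks(st, p$pre[i], p$suf[i]))
    } else {
      warning("edgemer ", p$e[i], " is not present; deletion ignored",
              call. = FALSE)
    }
  }
  validObject(st)
  st
}

#' Number of edges marked in the deletion buffer
#' @param st a [BufBoss-class].
#' @return integer.
#' @export
bdCount <- function(st) sum(st@bd)

# --- node tokens ------------------------------------------------------------

#' Make a node token for a nodemer label
#'
#' A token carries the label, the node's rank in the static index (NA when
#' absent) and its addition-buffer entry (NA masks when absent), and is the
#' handle for traversal of the modified graph.
#'
#' @param st a [BufBoss-class].
#' @param label nodemer label of length k-1.
#' @return A [NodeToken-class].
#' @export
makeToken <- function(st, label) {
  label <- toupper(label)
  if (nchar(label) != st@index@k - 1L)
    stop("token labels must be full nodemers of length k-1")
  .checkDna(label, "node label")
  i <- .haGet(st, label)
  new("NodeToken", label = label, rank = nodeSearch(st@index, label),
      inMask = if (is.na(i)) NA_integer_ else st@haIn[i],
      outMask = if (is.na(i)) NA_integer_ else st@haOut[i])
}

# does the (unmarked-deleted) in-edge at rank r come from a dummy node?
.inEdgeFromDummy <- function(index, r) {
  ch <- .edgeChar(index, r)
  p <- index@occ[[ch]][r - index@cTable[[ch]]]
  origin <- .edgeOrigin(index, p)
  nchar(nodeLabel(index, origin)) < index@k - 1L
}

#' Does a token's node exist in the modified graph?
#'
#' A node exists when its label is an addition-buffer key, or when it is in
#' the static index and still has a surviving (not marked deleted) real
#' edge.  Dummy in-edges do not count: a node whose real edges are all
#' deleted is no longer an endpoint of any edgemer even if its incoming
#' dummy chain is still physically present.
#'
#' @param st a [BufBoss-class].
#' @param token a [NodeToken-class].
#' @return logical.
#' @export
tokenExists <- function(st, token) {
  if (!is.na(token@inMask)) return(TRUE)      # buffered: case (i)
  v <- token@rank
  if (is.na(v)) return(FALSE)
  if (st@useMark && !st@mark[v]) return(TRUE) # untouched index node
  if (!any(st@bd)) return(TRUE)               # nothing deleted anywhere
  for (ch in outLabels(st@index, v))
    if (!st@bd[outEdgeRank(st@index, v, ch)]) return(TRUE)
  iv <- inEdgeInterval(st@index, v)
  if (!.isEmptyInterval(iv))
    for (r in iv[1L]:iv[2L])
      if (!st@bd[r] && !.inEdgeFromDummy(st@index, r)) return(TRUE)
  FALSE
}

#' Outgoing labels of a token's node in the modified graph
#'
#' The union of the static out-edge listing and the buffered outgoing
#' labels, minus the edges marked deleted.
#'
#' @inheritParams tokenExists
#' @return character vector of single-character labels, sorted.
#' @export
tokenOutLabels <- function(st, token) {
  if (!tokenExists(st, token))
    stop("node ", token@label, " does not exist in the modified graph")
  boss <- character(0)
  v <- token@rank
  if (!is.na(v)) {
    boss <- outLabels(st@index, v)
    if (any(st@bd) && !(st@useMark && !st@mark[v]) && length(boss) > 0L) {
      keep <- vapply(boss, function(ch)
        !st@bd[outEdgeRank(st@index, v, ch)], NA)
      boss <- boss[keep]
    }
  }
  buf <- if (is.na(token@outMask)) character(0)
         else .charsFromMask(token@outMask, .OUT_BIT)
  sort(unique(c(boss, buf)))
}

#' Traverse one edge of the modified graph
#'
#' Moves the token along the edge labeled \code{ch}; errors when the label
#' is not among [tokenOutLabels()].  The rank of the destination token is
#' obtained by a static traversal step when the static edge exists and is
#' not deleted; when the edge is buffer-only the destination may still be a
#' node of the static index, so its rank is recovered by node search (the
#' buffer alone cannot supply colexicographic ranks).  The buffer entry is
#' re-probed from the destination label.
#'
#' @inheritParams tokenExists
#' @param ch single character edge label.
#' @return The destination [NodeToken-class].
#' @export
tokenForward <- function(st, token, ch) {
  if (!(ch %in% tokenOutLabels(st, token)))
    stop("no outgoing edge labeled '", ch, "' from ", token@label)
  k <- st@index@k
  newLabel <- paste0(substr(token@label, 2L, k - 1L), ch)
  rank <- NA_integer_
  viaBoss <- FALSE
  if (!is.na(token@rank)) {
    r <- outEdgeRank(st@index, token@rank, ch)
    if (!is.na(r) && !st@bd[r]) {
      .navTick()
      rank <- .edgeDest(st@index, r)
      viaBoss <- TRUE
    }
  }
  if (!viaBoss) rank <- nodeSearch(st@index, newLabel)
  i <- .haGet(st, newLabel)
  new("NodeToken", label = newLabel, rank = rank,
      inMask = if (is.na(i)) NA_integer_ else st@haIn[i],
      outMask = if (is.na(i)) NA_integer_ else st@haOut[i])
}

# --- membership queries -----------------------------------------------------

#' Edgemer membership in the modified graph
#'
#' True when the edgemer is in the static index and not marked deleted, or
#' fully recorded in the addition buffer (prefix outgoing bit and suffix
#' incoming bit both set).
#'
#' @param st a [BufBoss-class].
#' @param e edgemers: character vector or [PackedKmers-class] of length-k
#'   strings.
#' @return logical vector, one element per edgemer.
#' @export
edgemerPresent <- function(st, e) {
  p <- .splitEdgemer(st, e)
  vapply(seq_along(p$e), function(i) {
    r <- edgeSearch(st@index, p$e[i])
    if (!is.na(r)) return(!st@bd[r])
    .haHasEdgemer(st, p$pre[i], p$lastc[i], p$suf[i], p$firstc[i])
  }, NA)
}

#' Query all edgemers of a read by graph traversal
#'
#' Reports membership of every edgemer of the read, reusing the previous
#' position's node token with a single forward step after each positive
#' answer, and restarting the search after a negative one.  The answers are
#' identical to independent [edgemerPresent()] calls, but an in-graph read
#' of m edgemers costs O(m) navigation steps instead of O(k*m).
#'
#' @param st a [BufBoss-class].
#' @param read a DNA string of length >= k.
#' @return logical vector with one element per edgemer of the read
#'   (length \code{nchar(read) - k + 1}); empty for shorter reads.
#' @export
queryRead <- function(st, read) {
  read <- toupper(read)
  .checkDna(read, "read")
  k <- st@index@k
  m <- nchar(read) - k + 1L
  if (m < 1L) return(logical(0))
  res <- logical(m)
  token <- NULL
  for (i in seq_len(m)) {
    ch <- substr(read, i + k - 1L, i + k - 1L)
    if (!is.null(token)) {
      if (ch %in% tokenOutLabels(st, token)) {
        res[i] <- TRUE
        token <- tokenForward(st, token, ch)
      } else {
        res[i] <- FALSE
        token <- NULL
      }
    } else {
      res[i] <- edgemerPresent(st, substr(read, i, i + k - 1L))
      if (res[i]) token <- makeToken(st, substr(read, i + 1L, i + k - 1L))
    }
  }
  res
}
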