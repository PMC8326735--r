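# Batched buffer flush: dummy preparation, merge planning by partition
# refinement over the implicit label matrices, merge execution, and dummy
# cleanup.  Flushing the buffers yields an index bit-identical to building
# directly from the modified edgemer set.

# --- phase 1: dummy preparation --------------------------------------------

# does node v (label lab) still have an outgoing edge in the modified graph?
.hasSurvivingOut <- function(st, v, lab) {
  i <- .haGet(st, lab)
  if (!is.na(i) && st@haOut[i] != 0L) return(TRUE)
  if (!is.na(v))
    for (ch in outLabels(st@index, v))
      if (!st@bd[outEdgeRank(st@index, v, ch)]) return(TRUE)
  FALSE
}

# record the incoming dummy chain of label S in the addition buffer:
# every proper prefix gets the outgoing bit toward the next character,
# every non-root chain node and S itself get the incoming '$' bit
.addDummyChain <- function(st, S) {
  len <- nchar(S)
  for (i in 0:(len - 1L)) {
    st <- .haSetBit(st, substr(S, 1L, i), "out",
                    substr(S, i + 1L, i + 1L))
    if (i > 0L) st <- .haSetBit(st, substr(S, 1L, i), "in", "$")
  }
  .haSetBit(st, S, "in", "$")
}

#' Dummy node preparation phase
#'
#' Determines which nodes of the modified graph will be left without any
#' incoming edge after the update, and records their incoming dummy chains
#' in the addition buffer.  Two sources are scanned: (a) every edge marked
#' in the deletion buffer whose destination loses all its incoming edges
#' without gaining a buffered one, and (b) every buffered nodemer that has
#' no incoming edge in either the buffer or the static index.  A chain is
#' only added for nodes that still have a surviving outgoing edge --
#' otherwise the node leaves the graph altogether.
#'
#' @param st a [BufBoss-class] with synchronized buffers.
#' @return The updated [BufBoss-class] (addition buffer extended).
#' @export
prepareDummies <- function(st) {
  idx <- st@index
  need <- character(0)
  # (a) iterate the deletion buffer in edge-rank order
  for (e in which(st@bd)) {
    v <- .edgeDest(idx, e)
    iv <- inEdgeInterval(idx, v)
    if (!all(st@bd[iv[1L]:iv[2L]])) next      # some in-edge survives
    S <- nodeLabel(idx, v)
    i <- .haGet(st, S)
    hasBufIn <- !is.na(i) &&
      bitwAnd(st@haIn[i], bitwNot(.IN_BIT[["$"]])) != 0L
    if (!hasBufIn && .hasSurvivingOut(st, v, S)) need <- c(need, S)
  }
  # (b) buffered nodemers with no incoming edge anywhere
  kk <- idx@k - 1L
  for (i in seq_along(st@haLabel)) {
    lab <- st@haLabel[i]
    if (nchar(lab) != kk) next
    if (st@haIn[i] != 0L) next                # buffered in-edge or chain done
    v <- nodeSearch(idx, lab)
    if (!is.na(v)) {
      iv <- inEdgeInterval(idx, v)
      if (!.isEmptyInterval(iv) && any(!st@bd[iv[1L]:iv[2L]])) next
    }
    if (.hasSurvivingOut(st, v, lab)) need <- c(need, lab)
  }
  for (S in unique(need)) st <- .addDummyChain(st, S)
  if (st@useMark) st <- .refreshMark(st, seq_len(idx@nNodes))
  st
}

# --- phase 2: merge planning ------------------------------------------------

#' Extract and sort the buffer matrix
#'
#' All addition-buffer keys, $-left-padded to width k-1 and sorted
#' colexicographically, with their in/out masks as satellite data.
#'
#' @param st a [BufBoss-class] (after [prepareDummies()] when flushing).
#' @return list with \code{labels} (unpadded), \code{padded}, \code{chars}
#'   (character matrix, one row per key), \code{inMask}, \code{outMask},
#'   all in colexicographic order; \code{n} number of rows.
#' @export
bufferMatrix <- function(st) {
  k <- st@index@k
  padded <- .padLabels(st@haLabel, k - 1L)
  ord <- .colexOrder(padded, k - 1L)
  padded <- padded[ord]
  chars <- if (length(padded) > 0L)
    matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
           ncol = k - 1L, byrow = TRUE)
  else matrix(character(0), nrow = 0L, ncol = k - 1L)
  list(labels = st@haLabel[ord], padded = padded, chars = chars,
       inMask = st@haIn[ord], outMask = st@haOut[ord], n = length(padded))
}

#' One column-propagation step of the implicit label matrix
#'
#' The label matrix of the static index (node labels as rows, one character
#' per column) is never materialized; its columns are produced right to
#' left.  Given column i, column i-1 is obtained by pushing each node's
#' character along all its outgoing edges (the destination's label is the
#' origin's shifted by one), with the root forced to '$'.
#'
#' @param index a [BossIndex-class].
#' @param col character vector of length \code{nNodes(index)}: the i-th
#'   column.
#' @return character vector: the (i-1)-th column.
#' @export
prevColumn <- function(index, col) {
  if (length(col) != index@nNodes)
    stop("column length must equal the number of nodes")
  new <- rep("$", index@nNodes)
  for (v in seq_len(index@nNodes)) {
    for (ch in outLabels(index, v)) {
      u <- .edgeDest(index, outEdgeRank(index, v, ch))
      new[u] <- col[v]
    }
  }
  new[1L] <- "$"
  new
}

# last column of the implicit label matrix: each node's in-edge label,
# '$' for indegree 0 (the root)
.lastColumn <- function(index) {
  vapply(seq_len(index@nNodes), function(v) {
    ch <- inLabel(index, v)
    if (is.na(ch)) "$" else ch
  }, "")
}

#' Merge planning by partition refinement
#'
#' Computes the colexicographic interleaving of the static index's node
#' labels and the buffer matrix rows as a sequence of half-open interval
#' pairs.  Starting from the single pair covering both row ranges, k-1
#' refinement rounds split every pair by the runs of characters in the next
#' column to the left (alphabet order $ < A < C < G < T); after the last
#' round each surviving pair groups rows with identical full padded labels,
#' so pairs with both sides non-empty are exactly the shared node labels.
#'
#' @param index a [BossIndex-class].
#' @param bm a buffer matrix from [bufferMatrix()].
#' @param trace also return the intermediate pair sequences after each
#'   refinement round (for property checking).
#' @return An integer matrix with one row per pair and columns
#'   \code{bossLo}, \code{bossHi}, \code{bufLo}, \code{bufHi} (half-open,
#'   1-based).  With \code{trace = TRUE}, a list with elements \code{plan}
#'   and \code{trace} (list of such matrices, one per round).
#' @export
planMerge <- function(index, bm, trace = FALSE) {
  k <- index@k
  nboss <- index@nNodes
  nbuf <- bm$n
  col <- .lastColumn(index)
  Q <- list(c(1L, nboss + 1L, 1L, nbuf + 1L))
  steps <- vector("list", k - 1L)
  for (t in seq_len(k - 1L)) {
    bufCol <- if (nbuf > 0L) bm$chars[, k - t] else character(0)
    Qnew <- vector("list", 0L)
    for (pair in Q) {
      x <- pair[1L]; a2 <- pair[2L]; y <- pair[3L]; b2 <- pair[4L]
      for (ch in .DNA_IN) {
        x2 <- x
        while (x2 < a2 && col[x2] == ch) x2 <- x2 + 1L
        y2 <- y
        while (y2 < b2 && bufCol[y2] == ch) y2 <- y2 + 1L
        if (x2 > x || y2 > y) Qnew[[length(Qnew) + 1L]] <- c(x, x2, y, y2)
        x <- x2; y <- y2
      }
    }
    Q <- Qnew
    steps[[t]] <- .pairsToMatrix(Q)
    if (t < k - 1L) col <- prevColumn(index, col)
  }
  plan <- .pairsToMatrix(Q)
  if (trace) list(plan = plan, trace = steps) else plan
}

.pairsToMatrix <- function(Q) {
  m <- if (length(Q) == 0L) matrix(integer(0), ncol = 4L)
       else do.call(rbind, Q)
  colnames(m) <- c("bossLo", "bossHi", "bufLo", "bufHi")
  m
}

# --- phase 3: merge execution -----------------------------------------------

#' Merge execution phase
#'
#' Streams the interval pairs of the plan in order, emitting for every node
#' of the updated graph its outgoing label set and indegree, and assembles
#' the new index from those.  Deletions are applied here: marked outgoing
#' edges leave the label set, and indegrees drop by the number of marked
#' incoming edges.  Shared nodes combine both sides; two bookkeeping rules
#' keep the result identical to a direct rebuild: a static-only node whose
#' edges are all deleted is not emitted (the root always is), and for a
#' shared row that is a dummy node of the static index the buffered '$'
#' in-bit is not counted again (its parent dummy edge already exists).
#'
#' @param index a [BossIndex-class].
#' @param bm a buffer matrix from [bufferMatrix()].
#' @param plan an interval-pair matrix from [planMerge()].
#' @param bd logical deletion flags over edge colexicographic ranks.
#' @return The merged [BossIndex-class] (before dummy cleanup).
#' @export
executeMerge <- function(index, bm, plan, bd) {
  stopifnot(length(bd) == index@nEdges)
  dummy <- .dummyFlags(index)
  outs <- vector("list", 0L)
  indegs <- integer(0)
  emit <- function(o, d) {
    outs[[length(outs) + 1L]] <<- o
    indegs[length(indegs) + 1L] <<- d
  }
  anyDel <- any(bd)
  bossNode <- function(v) {           # (outs minus deletions, in - deleted)
    o <- outLabels(index, v)
    if (anyDel && length(o) > 0L) {
      keep <- vapply(o, function(ch) !bd[outEdgeRank(index, v, ch)], NA)
      o <- o[keep]
    }
    iv <- inEdgeInterval(index, v)
    d <- if (.isEmptyInterval(iv)) 0L
         else sum(!bd[iv[1L]:iv[2L]])
    list(o = o, d = d)
  }
  bufIn <- function(j, dropDollar) {
    m <- bm$inMask[j]
    if (dropDollar) m <- bitwAnd(m, bitwNot(.IN_BIT[["$"]]))
    .popcount(m, .IN_BIT)
  }
  for (p in seq_len(nrow(plan))) {
    a <- plan[p, 1L]; a2 <- plan[p, 2L]
    b <- plan[p, 3L]; b2 <- plan[p, 4L]
    if (a2 - a == 1L && b2 - b == 1L) {       # shared node
      bn <- bossNode(a)
      o <- sort(unique(c(bn$o, .charsFromMask(bm$outMask[b], .OUT_BIT))))
      d <- bn$d + bufIn(b, dropDollar = dummy[a])
      if (length(o) > 0L || d > 0L || a == 1L) emit(o, d)
    } else if (a2 == a) {                     # buffer-only rows
      for (j in seq.int(b, length.out = b2 - b))
        emit(.charsFromMask(bm$outMask[j], .OUT_BIT),
             bufIn(j, dropDollar = FALSE))
    } else {                                  # static-only rows
      for (v in seq.int(a, length.out = a2 - a)) {
        bn <- bossNode(v)
        if (length(bn$o) > 0L || bn$d > 0L || v == 1L) emit(bn$o, bn$d)
      }
    }
  }
  .newBossIndex(index@k, outs, indegs)
}

# --- phase 4: dummy cleanup -------------------------------------------------

#' Remove redundant dummy chains
#'
#' Depth-first search of the dummy tree from the root.  A leaf dummy's
#' out-edge to a full node is redundant when that node has another incoming
#' edge (indegree >= 2), or when the node has left the graph entirely
#' (indegree 1 -- the dummy edge itself -- and outdegree 0).  A dummy whose
#' out-edges are all marked has its own in-edge marked, bottom-up.  The
#' final pass rewrites the index without the marked edges, decrementing the
#' indegrees of their destinations and dropping nodes left without any
#' edge; the edgemer set of the graph is unchanged.
#'
#' @param index a [BossIndex-class].
#' @return A [BossIndex-class] without redundant dummies (bit-identical to
#'   the input when there are none).
#' @export
cleanupDummies <- function(index) {
  n <- index@nNodes
  if (n == 1L) return(index)
  k <- index@k
  ind <- inDegrees(index)
  outd <- outDegrees(index)
  markedEdge <- logical(index@nEdges)
  dead <- logical(n)
  dfs <- function(v, depth) {               # returns TRUE if all outs marked
    labs <- outLabels(index, v)
    if (length(labs) == 0L) return(TRUE)
    all_marked <- TRUE
    for (ch in labs) {
      r <- outEdgeRank(index, v, ch)
      u <- .edgeDest(index, r)
      if (depth == k - 2L) {                # child is a full nodemer
        if (ind[u] >= 2L) {
          markedEdge[r] <<- TRUE
        } else if (ind[u] == 1L && outd[u] == 0L) {
          markedEdge[r] <<- TRUE            # target left the graph
          dead[u] <<- TRUE
        } else all_marked <- FALSE
      } else {                              # child is a dummy
        if (dfs(u, depth + 1L)) {
          markedEdge[r] <<- TRUE
          dead[u] <<- TRUE
        } else all_marked <- FALSE
      }
    }
    all_marked
  }
  dfs(1L, 0L)
  if (!any(markedEdge)) return(index)
  # decrement destination indegrees of the marked edges
  lostIn <- integer(n)
  for (r in which(markedEdge)) {
    u <- .edgeDest(index, r)
    lostIn[u] <- lostIn[u] + 1L
  }
  outs <- vector("list", 0L)
  indegs <- integer(0)
  for (v in seq_len(n)) {
    if (dead[v]) next
    labs <- outLabels(index, v)
    if (length(labs) > 0L) {
      keep <- vapply(labs, function(ch)
        !markedEdge[outEdgeRank(index, v, ch)], NA)
      labs <- labs[keep]
    }
    d <- ind[v] - lostIn[v]
    if (length(labs) == 0L && d == 0L && v != 1L) next
    outs[[length(outs) + 1L]] <- labs
    indegs[length(indegs) + 1L] <- d
  }
  .newBossIndex(k, outs, indegs)
}

# --- flushing ---------------------------------------------------------------

#' Flush the buffers into a new static index
#'
#' Runs the four update phases (dummy preparation, merge planning, merge
#' execution, dummy cleanup) and returns a state whose static index holds
#' the modified edgemer set and whose buffers are empty.  The result is
#' bit-identical to building the index directly from the modified set.
#'
#' @param st a [BufBoss-class].
#' @param cleanup run the dummy cleanup phase (default TRUE; without it,
#'   dummy chains made redundant by added in-edges are retained).
#' @return The flushed [BufBoss-class].
#' @export
flushBuffers <- function(st, cleanup = TRUE) {
  st2 <- prepareDummies(st)
  bm <- bufferMatrix(st2)
  plan <- planMerge(st2@index, bm)
  newIdx <- executeMerge(st2@index, bm, plan, st2@bd)
  if (isTRUE(cleanup)) newIdx <- cleanupDummies(newIdx)
  BufBoss(newIdx, threshold = st@threshold, useMark = st@useMark)
}

#' Flush when the addition buffer exceeds its threshold
#'
#' The buffers are flushed when the number of addition-buffer keys exceeds
#' the fraction \code{t} of the number of edges of the static index (or
#' unconditionally with \code{force}); otherwise the state is returned
#' unchanged.  This amortizes rebuild cost over many updates; t = 0 flushes
#' after every addition, t = 1 essentially never flushes.
#'
#' @param st a [BufBoss-class].
#' @param t flush threshold in [0,1]; defaults to the state's threshold.
#' @param force flush regardless of the threshold.
#' @param cleanup passed to [flushBuffers()].
#' @return A [BufBoss-class] (flushed or unchanged).
#' @export
flushIfNeeded <- function(st, t = st@threshold, force = FALSE,
                          cleanup = TRUE) {
  if (t < 0 || t > 1) stop("threshold must be in [0,1]")
  if (force || haSize(st) > t * st@index@nEdges)
    flushBuffers(st, cleanup = cleanup)
  else st
}
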