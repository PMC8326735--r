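# Construction of the static index from an edgemer set: context collection,
# dummy-tree closure, and assembly of the ebwt / O / I components.  The
# external-memory pipeline of large-scale builds (disk sort, parallel k-mer
# counting) is replaced by in-memory equivalents with the same output
# contract.

# Assemble a BossIndex from per-node (sorted outgoing labels, indegree) in
# colexicographic node order.  This is the single entry point through which
# construction, merge execution and dummy cleanup all produce indexes, which
# makes bit-exact equivalence between those paths meaningful.
.newBossIndex <- function(k, outs, indegs) {
  stopifnot(length(outs) == length(indegs), length(outs) >= 1L)
  indegs <- as.integer(indegs)
  ebwt <- as.character(unlist(outs, use.names = FALSE))
  outdeg <- as.integer(lengths(outs))
  # unary encoding: degree d becomes 1 followed by d zeros
  obits <- rep(rep(c(TRUE, FALSE), length(outdeg)), c(rbind(1L, outdeg)))
  ibits <- rep(rep(c(TRUE, FALSE), length(indegs)), c(rbind(1L, indegs)))
  cnt <- vapply(.DNA, function(ch) sum(ebwt == ch), 0L)
  C <- as.integer(cumsum(c(0L, cnt))[1:4])
  names(C) <- .DNA
  occ <- lapply(.DNA, function(ch) which(ebwt == ch))
  names(occ) <- .DNA
  new("BossIndex", k = as.integer(k), ebwt = ebwt,
      O = RankSelectBits(obits), I = RankSelectBits(ibits),
      cTable = C, occ = occ,
      nNodes = length(outs), nEdges = length(ebwt))
}

.coerceEdgemers <- function(edgemers, k) {
  if (is(edgemers, "PackedKmers")) edgemers <- decodeKmers(edgemers)
  edgemers <- toupper(as.character(edgemers))
  if (length(edgemers) > 0L) {
    .checkDna(edgemers, "edgemer")
    if (any(nchar(edgemers) != k))
      stop("all edgemers must have length k = ", k)
  }
  unique(edgemers)
}

.reverseStrings <- function(s)
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")

.sortContexts <- function(df, k) {
  padded <- .padLabels(df$nodemer, k - 1L)
  ord <- order(.reverseStrings(padded), df$side, df$char, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Collect nodemer contexts from an edgemer set
#'
#' Every edgemer c1..ck contributes two context triples: its prefix nodemer
#' with the last character on the right, and its suffix nodemer with the
#' first character on the left.  The set of left characters of a nodemer
#' determines its indegree; the set of right characters its outgoing labels.
#'
#' @param edgemers character vector or [PackedKmers-class] of edgemers.
#' @param k integer edgemer length.
#' @return data.frame with columns \code{nodemer}, \code{char}, \code{side}
#'   ("left"/"right"), deduplicated and sorted by the colexicographic order
#'   of the nodemer.
#' @export
collectContexts <- function(edgemers, k) {
  k <- as.integer(k)
  E <- .coerceEdgemers(edgemers, k)
  if (length(E) == 0L)
    return(data.frame(nodemer = character(0), char = character(0),
                      side = character(0), stringsAsFactors = FALSE))
  df <- data.frame(
    nodemer = c(substr(E, 1L, k - 1L), substr(E, 2L, k)),
    char = c(substr(E, k, k), substr(E, 1L, 1L)),
    side = rep(c("right", "left"), each = length(E)),
    stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  .sortContexts(df, k)
}

#' Close an edgemer set's contexts under the dummy tree
#'
#' Every nodemer with no left context needs an incoming chain of dummy nodes
#' spelling its proper prefixes down to the empty string, so that all
#' incoming paths of length k-1 spell the node label.  Prefixes shared
#' between chains are glued (deduplicated).  Dummy nodes other than the root
#' receive a single '$' left context; chain targets receive '$' as their
#' left context.
#'
#' @param contexts a context data.frame as produced by [collectContexts()].
#' @return data.frame of additional context rows in the same format.
#' @export
dummyClosure <- function(contexts) {
  empty <- data.frame(nodemer = character(0), char = character(0),
                      side = character(0), stringsAsFactors = FALSE)
  if (nrow(contexts) == 0L) return(empty)
  k <- max(nchar(contexts$nodemer)) + 1L
  haveLeft <- unique(contexts$nodemer[contexts$side == "left"])
  noLeft <- setdiff(unique(contexts$nodemer), haveLeft)
  if (length(noLeft) == 0L) return(empty)
  rows <- lapply(noLeft, function(x) {
    len <- nchar(x)
    pre <- substr(rep(x, len), 1L, 0:(len - 1L))   # proper prefixes, incl ""
    data.frame(
      nodemer = c(pre, pre[-1L], x),
      char = c(substring(x, 1:len, 1:len), rep("$", len)),
      side = c(rep("right", len), rep("left", len)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df), , drop = FALSE]
  .sortContexts(df, k)
}

#' Build the static index from an edgemer set
#'
#' Constructs the full Wheeler-graph index over the given edgemers,
#' including the dummy-node tree.  Construction is deterministic: outgoing
#' labels within a node are sorted ascending (the Wheeler order allows any
#' tie-break; the canonical one makes rebuilds bit-exact).  The root node
#' (empty string) is always materialized, even for fully cyclic graphs that
#' need no dummies, so that rank 1 is stable; an empty edgemer set yields the
#' root-only index.
#'
#' @param edgemers character vector or [PackedKmers-class] of distinct
#'   edgemers, all of length k.
#' @param k integer edgemer length, 2..32.
#' @return A [BossIndex-class].
#' @examples
#' idx <- buildIndex(decodeKmers(enumerateEdgemers("ACGTA", 4)), 4)
#' nNodes(idx)
#' @export
buildIndex <- function(edgemers, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 32L) stop("k must be in 2..32")
  E <- .coerceEdgemers(edgemers, k)
  ctx <- collectContexts(E, k)
  dum <- dummyClosure(ctx)
  all <- rbind(ctx, dum)
  all <- all[!duplicated(all), , drop = FALSE]
  nodes <- unique(c("", all$nodemer))
  padded <- .padLabels(nodes, k - 1L)
  nodes <- nodes[.colexOrder(padded, k - 1L)]
  ri <- all$side == "right"
  li <- all$side == "left"
  outsSplit <- split(all$char[ri],
                     factor(match(all$nodemer[ri], nodes),
                            levels = seq_along(nodes)))
  outs <- lapply(outsSplit, function(v) sort(unique(v)))
  indegs <- tabulate(match(all$nodemer[li], nodes), nbins = length(nodes))
  .newBossIndex(k, outs, indegs)
}
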