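# Brute-force reference implementation over plain string sets, and seeded
# synthetic-data generators.  The oracle shares no code with the succinct
# index: nodes, edges, degrees and orders are recomputed from explicit
# adjacency, so it can serve as independent ground truth for every index
# operation.  It is itself validated against a worked example with known
# printed degree sequences before being trusted.

#' Explicit reference graph for an edgemer set
#'
#' Builds the full edge-centric de Bruijn graph with its dummy tree as
#' explicit tables: nodes (with padded labels) in colexicographic order,
#' edges in colexicographic order with origin/destination, degrees, and the
#' materialized label matrix.
#'
#' @param edgemers character vector or [PackedKmers-class] of edgemers.
#' @param k edgemer length.
#' @return list with components:
#'   \describe{
#'     \item{nodes}{data.frame(label, padded, outDegree, inDegree), rows in
#'       colexicographic node order (rank = row number).}
#'     \item{edges}{data.frame(origin, char, dest, padded), rows in
#'       colexicographic edge order (rank = row number); origin/dest are
#'       node labels.}
#'     \item{mboss}{character matrix: padded node labels, one character per
#'       column.}
#'     \item{k}{the edgemer length.}
#'   }
#' @export
oracleGraph <- function(edgemers, k) {
  k <- as.integer(k)
  if (is(edgemers, "PackedKmers")) edgemers <- decodeKmers(edgemers)
  E <- unique(toupper(as.character(edgemers)))
  stopifnot(all(nchar(E) == k))
  pre <- substr(E, 1L, k - 1L)
  suf <- substr(E, 2L, k)
  full <- unique(c(pre, suf))
  # real edges
  edges <- data.frame(origin = pre, char = substr(E, k, k), dest = pre,
                      stringsAsFactors = FALSE)
  edges$dest <- suf
  # dummy chains for nodes without a predecessor edgemer
  noIn <- full[!(full %in% suf)]
  dummies <- character(0)
  for (x in noIn) {
    len <- nchar(x)
    chain <- substr(rep(x, len + 1L), 1L, 0:len)   # "", prefixes, x itself
    dummies <- c(dummies, chain[-(len + 1L)])
    edges <- rbind(edges, data.frame(
      origin = chain[1:len],
      char = substring(x, 1:len, 1:len),
      dest = chain[2:(len + 1L)], stringsAsFactors = FALSE))
  }
  edges <- edges[!duplicated(edges[c("origin", "char")]), , drop = FALSE]
  labels <- unique(c("", full, dummies))
  if (length(E) == 0L) { labels <- ""; edges <- edges[0, , drop = FALSE] }
  padded <- .oraclePad(labels, k - 1L)
  ord <- order(.oracleRev(padded), method = "radix")
  labels <- labels[ord]; padded <- padded[ord]
  nodes <- data.frame(
    label = labels, padded = padded,
    outDegree = as.integer(table(factor(edges$origin, levels = labels))),
    inDegree = as.integer(table(factor(edges$dest, levels = labels))),
    stringsAsFactors = FALSE)
  edges$padded <- .oraclePad(paste0(edges$origin, edges$char), k)
  edges <- edges[order(.oracleRev(edges$padded), method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  mboss <- if (k >= 2L && length(labels) > 0L)
    matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
           ncol = k - 1L, byrow = TRUE)
  else matrix(character(0), nrow = length(labels), ncol = 0L)
  list(nodes = nodes, edges = edges, mboss = mboss, k = k)
}

.oraclePad <- function(labels, width)
  paste0(strrep("$", width - nchar(labels)), labels)

.oracleRev <- function(s)
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")

#' Set-semantics oracle for an update script
#'
#' Maintains the plain edgemer set under a script of additions and
#' deletions: the final set is (E with all adds applied) minus the deletes,
#' in script order (adding an existing edgemer or deleting an absent one is
#' a no-op).
#'
#' @param edgemers initial edgemer set (character vector).
#' @param script data.frame with columns \code{op} ("add"/"del") and
#'   \code{edgemer}.
#' @return character vector: the final edgemer set (unordered).
#' @export
oracleDynamic <- function(edgemers, script) {
  S <- unique(toupper(as.character(edgemers)))
  for (i in seq_len(nrow(script))) {
    e <- toupper(script$edgemer[i])
    if (script$op[i] == "add") S <- union(S, e)
    else S <- setdiff(S, e)
  }
  S
}

#' Seeded random genomes, reads and update scripts
#'
#' Generates a uniform random ACGT genome, reads sampled from it with
#' replacement, and an interleaved add/delete script: additions are the
#' edgemers of short random sequences (novel with high probability),
#' deletions are drawn from the evolving edgemer set (with
#' \code{strict = TRUE}, only currently-present edgemers are ever deleted).
#' Fully reproducible from the seed; the global RNG state is restored.
#'
#' @param seed integer seed.
#' @param genomeLen genome length in bases.
#' @param nReads,readLen number and length of reads.
#' @param k edgemer length.
#' @param nAdd,nDel number of addition / deletion events in the script.
#' @param strict never request deletion of an absent edgemer.
#' @return list with \code{genome}, \code{reads} (character vector),
#'   \code{edgemers} (of the reads), \code{script} (data.frame op/edgemer)
#'   and \code{k}.
#' @export
randomInstance <- function(seed, genomeLen = 300L, nReads = 20L,
                           readLen = 50L, k = 5L, nAdd = 10L, nDel = 10L,
                           strict = TRUE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  readLen <- min(readLen, genomeLen)
  genome <- paste(sample(.DNA, genomeLen, replace = TRUE), collapse = "")
  starts <- sample.int(genomeLen - readLen + 1L, nReads, replace = TRUE)
  reads <- substring(genome, starts, starts + readLen - 1L)
  base <- decodeKmers(enumerateEdgemers(reads, k))
  current <- base
  ops <- character(0); mers <- character(0)
  nEvents <- nAdd + nDel
  isAdd <- sample(rep(c(TRUE, FALSE), c(nAdd, nDel)))
  for (ev in seq_len(nEvents)) {
    if (isAdd[ev]) {
      piece <- paste(sample(.DNA, k + sample.int(6L, 1L) - 1L,
                            replace = TRUE), collapse = "")
      for (e in decodeKmers(enumerateEdgemers(piece, k))) {
        ops <- c(ops, "add"); mers <- c(mers, e)
        current <- union(current, e)
      }
    } else {
      pool <- if (strict) current
              else unique(c(current, paste(sample(.DNA, k, replace = TRUE),
                                           collapse = "")))
      if (length(pool) == 0L) next
      e <- sample(pool, 1L)
      ops <- c(ops, "del"); mers <- c(mers, e)
      current <- setdiff(current, e)
    }
  }
  list(genome = genome, reads = reads, edgemers = base,
       script = data.frame(op = ops, edgemer = mers,
                           stringsAsFactors = FALSE),
       k = k)
}

#' Worked-example fixture strings
#'
#' The four strings of the small worked example used throughout the
#' documentation and tests: with k = 4 they induce a 13-node graph (8
#' edgemers plus a 4-node dummy tree and 5 dummy edges) whose node order,
#' degree sequences and ebwt are known exactly.
#'
#' @return character vector of four DNA strings.
#' @export
exampleReads <- function() c("ACGTA", "ACACGT", "AGTA", "GCGCGCGA")

#' Worked-example update script
#'
#' The companion update to [exampleReads()]: add the edgemers of one new
#' sequence and delete three existing edgemers, exercising a new dummy
#' chain (the node GCG loses its only incoming edge) and cleanup of
#' redundant dummies.
#'
#' @return list with \code{add} (a sequence whose edgemers are added) and
#'   \code{delete} (edgemers to delete).
#' @export
exampleUpdate <- function()
  list(add = "CGCACAGT", delete = c("CGCG", "CGTA", "ACAC"))
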