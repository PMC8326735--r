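# Shared fixtures and naive string-level oracles for the test suite.
# The oracles here deliberately use plain string slicing / sorting and no
# package internals, so they stay independent of the code paths they check.

g1Strings <- function() exampleReads()

g1Edgemers <- function() sort(decodeKmers(enumerateEdgemers(g1Strings(), 4)))

g1Index <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildIndex(g1Edgemers(), 4)
    cache
  }
})

# node labels of the worked example in colexicographic order (known exactly)
g1NodeOrder <- function()
  c("", "A", "ACA", "CGA", "GTA", "AC", "CAC", "CGC", "AG", "ACG", "GCG",
    "AGT", "CGT")

# edge labels of the worked example in colexicographic edge order
g1EdgeOrder <- function()
  c("A", "ACA", "GCGA", "AGTA", "CGTA", "AC", "ACAC", "GCGC", "AG",
    "CACG", "CGCG", "AGT", "ACGT")

g1UpdatedSet <- function() {
  up <- exampleUpdate()
  adds <- decodeKmers(enumerateEdgemers(up$add, 4))
  oracleDynamic(g1Edgemers(),
                data.frame(op = c(rep("add", length(adds)),
                                  rep("del", length(up$delete))),
                           edgemer = c(adds, up$delete),
                           stringsAsFactors = FALSE))
}

# naive k-mer listing by string slicing (oracle for enumerateEdgemers)
naiveEdgemers <- function(seqs, k, addRc = FALSE) {
  rc1 <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                        "")[[1]]), collapse = "")
  pieces <- unlist(lapply(toupper(seqs), function(s)
    strsplit(gsub("[^ACGT]", " ", s), " +")[[1]]))
  pieces <- pieces[nzchar(pieces)]
  if (addRc) pieces <- c(pieces, vapply(pieces, rc1, ""))
  out <- character(0)
  for (p in pieces) {
    n <- nchar(p)
    if (n >= k) out <- c(out, substring(p, 1:(n - k + 1), k:n))
  }
  sort(unique(out))
}

# string-level reverse complement (oracle for the packed implementation)
naiveRc <- function(s)
  vapply(strsplit(chartr("ACGT", "TGCA", s), ""),
         function(ch) paste(rev(ch), collapse = ""), "")

randomKmers <- function(n, k)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""), "")

# list the (real) edgemers represented by an index: every full node's label
# extended by each of its outgoing labels
indexEdgemers <- function(idx) {
  k <- edgemerLength(idx)
  out <- character(0)
  for (v in seq_len(nNodes(idx))) {
    lab <- nodeLabel(idx, v)
    if (nchar(lab) < k - 1) next
    for (ch in outLabels(idx, v)) out <- c(out, paste0(lab, ch))
  }
  sort(out)
}

# a fake buffer matrix (as produced by bufferMatrix) from raw labels,
# for exercising planMerge against arbitrary row sets
fakeBufferMatrix <- function(labels, k) {
  pad <- paste0(strrep("$", (k - 1) - nchar(labels)), labels)
  ord <- order(vapply(strsplit(pad, ""),
                      function(ch) paste(rev(ch), collapse = ""), ""),
               method = "radix")
  pad <- pad[ord]
  chars <- if (length(pad) > 0)
    matrix(unlist(strsplit(pad, "")), ncol = k - 1, byrow = TRUE)
  else matrix(character(0), 0, k - 1)
  list(labels = labels[ord], padded = pad, chars = chars,
       inMask = integer(length(pad)), outMask = integer(length(pad)),
       n = length(pad))
}

# replay an update script on a BufBoss and on the plain set in parallel
replayScript <- function(st, script, probeEachStep = 0) {
  cur <- indexEdgemers(st@index)
  for (i in seq_len(nrow(script))) {
    em <- script$edgemer[i]
    if (script$op[i] == "add") {
      st <- addEdgemers(st, em)
      cur <- union(cur, em)
    } else {
      st <- suppressWarnings(deleteEdgemers(st, em))
      cur <- setdiff(cur, em)
    }
    if (probeEachStep > 0) {
      pool <- unique(c(em, cur))
      probe <- pool[sample.int(length(pool), min(probeEachStep, length(pool)))]
      probe <- unique(c(probe, randomKmers(2, nchar(em))))
      expect_identical(edgemerPresent(st, probe), probe %in% cur,
                       label = paste("membership after step", i))
    }
  }
  list(st = st, set = cur)
}
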