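# The four update phases and the flush pipeline.

test_that("dummy preparation records chains for nodes losing all in-edges", {
  up <- exampleUpdate()
  st <- BufBoss(g1Index())
  st <- addEdgemers(st, decodeKmers(enumerateEdgemers(up$add, 4)))
  st <- deleteEdgemers(st, up$delete)
  st2 <- prepareDummies(st)
  # GCG loses its only in-edge (CGCG) and gains none: chain eps, G, GC,
  # plus GCG itself entering the buffer with the incoming-$ bit
  newKeys <- setdiff(st2@haLabel, st@haLabel)
  expect_setequal(newKeys, c("", "G", "GC", "GCG"))
  expect_identical(haEntry(st2, "G")$inBits, "10000")
  expect_identical(haEntry(st2, "GC")$outBits, "0010")
  expect_identical(substr(haEntry(st2, "GCG")$inBits, 1, 1), "1")
  # CAC loses ACAC but gains GCAC from the buffer: no chain
  expect_identical(substr(haEntry(st2, "CAC")$inBits, 1, 1), "0")
  # empty deletion buffer, no sourceless keys: nothing changes
  # (GTA keeps its static in-edges, TAC gains a buffered one)
  st3 <- addEdgemers(BufBoss(g1Index()), "GTAC")
  st4 <- prepareDummies(st3)
  expect_identical(st4@haLabel, st3@haLabel)
  expect_identical(st4@haIn, st3@haIn)
})

test_that("a buffered nodemer with no incoming edge gets the dollar bit", {
  st <- BufBoss(buildIndex(character(0), 4))
  st <- addEdgemers(st, "ACAG")
  expect_identical(haEntry(st, "ACA")$inBits, "00000")
  st <- prepareDummies(st)
  expect_identical(haEntry(st, "ACA")$inBits, "10000")  # incoming dollar
  expect_setequal(st@haLabel, c("", "A", "AC", "ACA", "CAG"))
})

test_that("the buffer matrix pads and sorts keys colexicographically", {
  st <- BufBoss(buildIndex(character(0), 4))
  for (lab in c("CAG", "ACA", "")) st <- bufdbg:::.haSetBit(st, lab, "in", "$")
  st@haIn[st@haLabel == ""] <- 0L
  st@haOut[st@haLabel == ""] <- 1L     # keep the root entry non-empty
  bm <- bufferMatrix(st)
  expect_identical(bm$padded, c("$$$", "ACA", "CAG"))
  # order agrees with a reversed-string sort oracle
  pads <- c("$$$", "ACA", "CAG")
  expect_identical(bm$padded,
                   pads[order(vapply(strsplit(pads, ""), function(ch)
                     paste(rev(ch), collapse = ""), ""))])
  expect_identical(bufferMatrix(BufBoss(g1Index()))$n, 0L)
  expect_false(anyDuplicated(bm$padded) > 0)
})

test_that("column propagation reproduces the label matrix right to left", {
  idx <- g1Index()
  last <- bufdbg:::.lastColumn(idx)
  expect_identical(paste(last, collapse = ""), "$AAAACCCGGGTT")
  expect_identical(paste(prevColumn(idx, last), collapse = ""),
                   "$$CGTAAGACCGG")
  eps <- buildIndex(character(0), 4)
  expect_identical(prevColumn(eps, "$"), "$")
  expect_error(prevColumn(idx, c("$", "A")), "length")
  # all columns of the materialized matrix are recovered in sequence
  set.seed(51)
  for (rep in 1:10) {
    k <- sample(3:7, 1)
    inst <- randomInstance(seed = 700 + rep, genomeLen = 120, nReads = 4,
                           readLen = 40, k = k, nAdd = 0, nDel = 0)
    idx2 <- buildIndex(inst$edgemers, k)
    og <- oracleGraph(inst$edgemers, k)
    col <- bufdbg:::.lastColumn(idx2)
    for (j in seq.int(k - 1, 1)) {
      expect_identical(col, og$mboss[, j])
      if (j > 1) col <- prevColumn(idx2, col)
    }
  }
})

test_that("merge planning refines to the exact label interleaving", {
  idx <- g1Index()
  # empty buffer: one singleton pair per node
  plEmpty <- planMerge(idx, bufferMatrix(BufBoss(idx)))
  expect_identical(nrow(plEmpty), 13L)
  expect_true(all(plEmpty[, 2] - plEmpty[, 1] == 1))
  expect_true(all(plEmpty[, 4] == plEmpty[, 3]))
  # buffer equal to the index's own labels: every pair fully shared
  og <- oracleGraph(g1Edgemers(), 4)
  bmAll <- fakeBufferMatrix(og$nodes$label, 4)
  plAll <- planMerge(idx, bmAll)
  expect_identical(nrow(plAll), 13L)
  expect_true(all(plAll[, 2] - plAll[, 1] == 1 &
                  plAll[, 4] - plAll[, 3] == 1))
  expect_identical(plAll[, 1], plAll[, 3])
  # worked update: classification matches a string-level merge
  up <- exampleUpdate()
  st <- BufBoss(idx)
  st <- addEdgemers(st, decodeKmers(enumerateEdgemers(up$add, 4)))
  st <- deleteEdgemers(st, up$delete)
  st <- prepareDummies(st)
  bm <- bufferMatrix(st)
  pl <- planMerge(idx, bm)
  bossPadded <- og$nodes$padded
  shared <- pl[pl[, 2] > pl[, 1] & pl[, 4] > pl[, 3], , drop = FALSE]
  expect_setequal(bossPadded[shared[, 1]],
                  intersect(bossPadded, bm$padded))
  bufOnly <- pl[pl[, 2] == pl[, 1], , drop = FALSE]
  expect_setequal(bm$padded[bufOnly[, 3]], setdiff(bm$padded, bossPadded))
})

test_that("interval pairs satisfy the partition-refinement properties", {
  set.seed(52)
  for (rep in 1:8) {
    k <- sample(3:6, 1)
    inst <- randomInstance(seed = 800 + rep, genomeLen = 80, nReads = 4,
                           readLen = 30, k = k, nAdd = 8, nDel = 5)
    st <- BufBoss(buildIndex(inst$edgemers, k))
    st <- replayScript(st, inst$script)$st
    st <- prepareDummies(st)
    bm <- bufferMatrix(st)
    og <- oracleGraph(indexEdgemers(st@index), k)
    res <- planMerge(st@index, bm, trace = TRUE)
    for (t in seq_along(res$trace)) {
      Q <- res$trace[[t]]
      dimnames(Q) <- NULL
      # property 1: both sides tile their full ranges in order
      expect_identical(Q[1, 1], 1L)
      expect_identical(Q[nrow(Q), 2], nNodes(st@index) + 1L)
      expect_identical(Q[1, 3], 1L)
      expect_identical(Q[nrow(Q), 4], bm$n + 1L)
      if (nrow(Q) > 1) {
        expect_identical(Q[-1, 1], Q[-nrow(Q), 2])
        expect_identical(Q[-1, 3], Q[-nrow(Q), 4])
      }
      sufB <- apply(og$mboss[, seq.int(k - t, k - 1), drop = FALSE], 1,
                    paste, collapse = "")
      sufQ <- if (bm$n > 0)
        apply(bm$chars[, seq.int(k - t, k - 1), drop = FALSE], 1,
              paste, collapse = "")
      else character(0)
      for (p in seq_len(nrow(Q))) {
        rowsB <- if (Q[p, 2] > Q[p, 1]) sufB[Q[p, 1]:(Q[p, 2] - 1)]
                 else character(0)
        rowsQ <- if (Q[p, 4] > Q[p, 3]) sufQ[Q[p, 3]:(Q[p, 4] - 1)]
                 else character(0)
        # property 2: equal suffixes within a pair
        expect_lte(length(unique(c(rowsB, rowsQ))), 1)
        # properties 3-4: maximality against the next pair
        if (p < nrow(Q)) {
          nxt <- c(if (Q[p + 1, 2] > Q[p + 1, 1]) sufB[Q[p + 1, 1]],
                   if (Q[p + 1, 4] > Q[p + 1, 3]) sufQ[Q[p + 1, 3]])
          if (length(c(rowsB, rowsQ)) > 0 && length(nxt) > 0)
            expect_false(unique(c(rowsB, rowsQ))[1] %in% nxt)
        }
      }
    }
  }
})

test_that("merge execution applies deletions and is the identity when idle", {
  idx <- g1Index()
  st <- BufBoss(idx)
  merged <- executeMerge(idx, bufferMatrix(st), planMerge(idx,
            bufferMatrix(st)), st@bd)
  expect_true(bossIdentical(merged, idx))
  # deletions only: CGTA removed drops GTA's indegree from 2 to 1
  st2 <- deleteEdgemers(st, "CGTA")
  m2 <- executeMerge(idx, bufferMatrix(st2), planMerge(idx,
         bufferMatrix(st2)), st2@bd)
  expect_identical(nEdges(m2), 12L)
  gta <- which(vapply(seq_len(nNodes(m2)), function(v)
    nodeLabel(m2, v), "") == "GTA")
  expect_identical(inDegrees(m2)[gta], 1L)
})

test_that("cleanup removes exactly the chains made redundant", {
  # TACA gives ACA a real in-edge; its chain through AC becomes redundant,
  # while A and the AG chain are still needed
  st <- addEdgemers(BufBoss(g1Index()), "TACA")
  fl <- flushBuffers(st)
  direct <- buildIndex(c(g1Edgemers(), "TACA"), 4)
  expect_true(bossIdentical(fl@index, direct))
  labs <- vapply(seq_len(nNodes(fl@index)), function(v)
    nodeLabel(fl@index, v), "")
  expect_false("AC" %in% labs)
  expect_true(all(c("A", "AG", "ACA") %in% labs))
  # no-op on indexes without redundant dummies
  expect_true(bossIdentical(cleanupDummies(g1Index()), g1Index()))
  eps <- buildIndex(character(0), 4)
  expect_true(bossIdentical(cleanupDummies(eps), eps))
  # edgemer set is always preserved
  set.seed(53)
  for (rep in 1:10) {
    inst <- randomInstance(seed = 900 + rep, genomeLen = 100, nReads = 4,
                           readLen = 30, k = 4, nAdd = 0, nDel = 0)
    idx <- buildIndex(inst$edgemers, 4)
    expect_identical(indexEdgemers(cleanupDummies(idx)), indexEdgemers(idx))
  }
})

test_that("flushing respects the buffer-fraction threshold", {
  st <- addEdgemers(BufBoss(g1Index()), c("ACAA", "ACAG", "TACA"))
  expect_identical(haSize(st), 4L)   # keys ACA (in+out), CAA, CAG, TAC
  stT1 <- flushIfNeeded(st, t = 1)
  expect_identical(haSize(stT1), haSize(st))   # 4 <= 13: no flush
  stT0 <- flushIfNeeded(st, t = 0)
  expect_identical(haSize(stT0), 0L)
  expect_true(edgemerPresent(stT0, "ACAA"))
  stF <- flushIfNeeded(st, t = 1, force = TRUE)
  expect_true(bossIdentical(stF@index, stT0@index))
  expect_error(flushIfNeeded(st, t = 2), "threshold")
})

test_that("flush equals a direct rebuild on targeted edge cases", {
  E <- g1Edgemers()
  # chain-fed node loses its only out-edge: node and chain must vanish
  st <- deleteEdgemers(BufBoss(g1Index()), "ACAC")
  expect_true(bossIdentical(flushBuffers(st)@index,
                            buildIndex(setdiff(E, "ACAC"), 4)))
  # delete everything: the root-only index remains
  st2 <- deleteEdgemers(BufBoss(g1Index()), E)
  expect_true(bossIdentical(flushBuffers(st2)@index,
                            buildIndex(character(0), 4)))
  # grow from empty
  st3 <- addEdgemers(BufBoss(buildIndex(character(0), 4)),
                     c("ACGT", "CGTA", "TTTT"))
  expect_true(bossIdentical(flushBuffers(st3)@index,
                            buildIndex(c("ACGT", "CGTA", "TTTT"), 4)))
  # deletion kills a whole chain while an addition needs a fresh one
  st4 <- deleteEdgemers(BufBoss(g1Index()), "AGTA")
  st4 <- addEdgemers(st4, "GTTT")
  expect_true(bossIdentical(flushBuffers(st4)@index,
              buildIndex(c(setdiff(E, "AGTA"), "GTTT"), 4)))
  # buffered chain gluing onto an existing static dummy: ATT's chain shares
  # the dummy A with the static tree (its parent edge must not be counted
  # twice)
  st4b <- addEdgemers(BufBoss(g1Index()), "ATTT")
  expect_true(bossIdentical(flushBuffers(st4b)@index,
              buildIndex(c(E, "ATTT"), 4)))
  # cleanup off: redundant chains are retained but the edgemer set matches
  st5 <- addEdgemers(BufBoss(g1Index()), "TACA")
  noClean <- flushBuffers(st5, cleanup = FALSE)
  expect_identical(indexEdgemers(noClean@index),
                   sort(c(E, "TACA")))
  expect_gt(nNodes(noClean@index),
            nNodes(buildIndex(c(E, "TACA"), 4)))
})
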