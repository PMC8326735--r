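# Addition/deletion buffers, node tokens, and membership on the modified
# graph.

test_that("buffered edgemers set the documented indicator bits", {
  st <- BufBoss(buildIndex(character(0), 4))
  st <- addEdgemers(st, c("ACAA", "ACAG", "TACA"))
  e <- haEntry(st, "ACA")
  expect_identical(e$outBits, "1010")   # outgoing A and G over ACGT
  expect_identical(e$inBits, "00001")   # incoming T over $ACGT
  # adding the same edgemers again changes nothing
  st2 <- addEdgemers(st, c("ACAA", "TACA"))
  expect_identical(st2@haLabel, st@haLabel)
  expect_identical(st2@haIn, st@haIn)
  expect_identical(st2@haOut, st@haOut)
})

test_that("the buffers stay synchronized under deletes and re-adds", {
  st <- BufBoss(g1Index())
  st <- deleteEdgemers(st, "CGCG")
  expect_true(st@bd[11])
  expect_identical(bdCount(st), 1L)
  st <- addEdgemers(st, "CGCG")        # re-add only clears the mark
  expect_false(st@bd[11])
  expect_identical(haSize(st), 0L)
  # add then delete a novel edgemer cancels out
  st <- addEdgemers(st, "ACAG")
  expect_identical(haEntry(st, "ACA")$outBits, "0010")
  st <- deleteEdgemers(st, "ACAG")
  expect_identical(haSize(st), 0L)
  # deleting an absent edgemer warns and leaves the state unchanged
  expect_warning(st2 <- deleteEdgemers(st, "AAAA"), "ignored")
  expect_identical(st2@bd, st@bd)
  expect_identical(st2@haLabel, st@haLabel)
})

test_that("addition set, deletion set and index stay disjoint under random scripts", {
  set.seed(41)
  for (rep in 1:30) {
    k <- sample(2:6, 1)
    inst <- randomInstance(seed = 500 + rep, genomeLen = 100, nReads = 4,
                           readLen = 30, k = k, nAdd = 6, nDel = 6,
                           strict = FALSE)
    st <- BufBoss(buildIndex(inst$edgemers, k))
    out <- replayScript(st, inst$script)
    st <- out$st
    # D subset of E by construction; check A is disjoint from E: every fully
    # buffered edgemer must be absent from the static index
    for (i in seq_along(st@haLabel)) {
      lab <- st@haLabel[i]
      if (nchar(lab) != k - 1) next
      for (ch in c("A", "C", "G", "T")) {
        if (bitwAnd(st@haOut[i], bufdbg:::.OUT_BIT[[ch]]) == 0) next
        em <- paste0(lab, ch)
        suf <- substr(em, 2, k)
        j <- match(suf, st@haLabel)
        fullyBuffered <- !is.na(j) &&
          bitwAnd(st@haIn[j], bufdbg:::.IN_BIT[[substr(em, 1, 1)]]) != 0
        if (fullyBuffered)
          expect_true(is.na(edgeSearch(st@index, em)))
      }
    }
    expect_identical(sort(edgemerPresent(st, out$set)), rep(TRUE,
                     length(out$set)))
  }
})

test_that("tokens report rank and buffer entry independently", {
  st <- BufBoss(g1Index())
  t1 <- makeToken(st, "ACA")
  expect_identical(t1@rank, 3L)
  expect_true(is.na(t1@inMask))
  st <- addEdgemers(st, "TCAG")        # buffered-only nodemer CAG
  t2 <- makeToken(st, "CAG")
  expect_true(is.na(t2@rank))
  expect_false(is.na(t2@inMask))
  t3 <- makeToken(st, "TTT")
  expect_true(is.na(t3@rank) && is.na(t3@inMask))
  expect_error(makeToken(st, "TT"), "k-1")
})

test_that("node existence accounts for deletions and the dummy tree", {
  st <- BufBoss(g1Index())
  stBoth <- deleteEdgemers(st, c("AGTA", "CGTA"))
  expect_false(tokenExists(stBoth, makeToken(stBoth, "GTA")))
  stOne <- deleteEdgemers(st, "CGTA")
  expect_true(tokenExists(stOne, makeToken(stOne, "GTA")))
  stBuf <- addEdgemers(st, "TCAG")
  expect_true(tokenExists(stBuf, makeToken(stBuf, "CAG")))
  # a chain-fed node whose only real edge is deleted leaves the graph even
  # though its dummy in-edge physically remains
  stDead <- deleteEdgemers(st, "ACAC")
  expect_false(tokenExists(stDead, makeToken(stDead, "ACA")))
})

test_that("token out-labels merge index and buffer minus deletions", {
  st <- addEdgemers(BufBoss(g1Index()), "ACAG")
  expect_identical(tokenOutLabels(st, makeToken(st, "ACA")), c("C", "G"))
  st2 <- deleteEdgemers(st, "ACAC")
  expect_identical(tokenOutLabels(st2, makeToken(st2, "ACA")), "G")
  expect_identical(tokenOutLabels(st, makeToken(st, "CGA")), character(0))
})

test_that("token traversal steps through static and buffered edges", {
  st <- BufBoss(g1Index())
  tk <- tokenForward(st, makeToken(st, "CGC"), "G")
  expect_identical(tk@label, "GCG")
  expect_identical(tk@rank, 11L)
  st2 <- addEdgemers(st, "ACAG")
  tk2 <- tokenForward(st2, makeToken(st2, "ACA"), "G")
  expect_identical(tk2@label, "CAG")
  expect_true(is.na(tk2@rank))          # CAG is in neither index nor buffer
  expect_error(tokenForward(st, makeToken(st, "CGA"), "A"), "no outgoing")
})

test_that("edgemer membership sees the modified edge set", {
  st <- BufBoss(g1Index())
  expect_true(edgemerPresent(st, "ACGT"))
  st <- deleteEdgemers(st, "CGCG")
  expect_false(edgemerPresent(st, "CGCG"))
  st <- addEdgemers(st, "ACAG")
  expect_true(edgemerPresent(st, "ACAG"))
  expect_identical(edgemerPresent(st, c("ACGT", "CGCG", "ACAG", "TTTT")),
                   c(TRUE, FALSE, TRUE, FALSE))
})

test_that("read queries equal independent searches, with and without marks", {
  st <- BufBoss(g1Index())
  expect_identical(queryRead(st, "ACACGT"), c(TRUE, TRUE, TRUE))
  expect_identical(queryRead(st, "TTTTT"), c(FALSE, FALSE))
  expect_identical(queryRead(st, "ACG"), logical(0))
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(3:7, 1)
    inst <- randomInstance(seed = 600 + rep, genomeLen = 150, nReads = 5,
                           readLen = 50, k = k, nAdd = 5, nDel = 5)
    stP <- BufBoss(buildIndex(inst$edgemers, k), useMark = FALSE)
    stM <- BufBoss(buildIndex(inst$edgemers, k), useMark = TRUE)
    stP <- replayScript(stP, inst$script)$st
    stM <- replayScript(stM, inst$script)$st
    reads <- c(inst$reads[1:3],
               paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""))
    for (rd in reads) {
      m <- nchar(rd) - k + 1
      want <- edgemerPresent(stP, substring(rd, 1:m, k:nchar(rd)))
      expect_identical(queryRead(stP, rd), want)
      expect_identical(queryRead(stM, rd), want)   # accelerator-free parity
    }
  }
})

test_that("a buffered bridge into the static graph keeps traversal exact", {
  # static graph holds GTAC; the read reaches it through buffer-only edges,
  # so the traversal must recover the static rank mid-read
  st <- BufBoss(buildIndex(c("GTAC", "TACA"), 4))
  st <- addEdgemers(st, c("CAGT", "AGTA"))
  rd <- "CAGTACA"
  m <- nchar(rd) - 4 + 1
  expect_identical(queryRead(st, rd),
                   edgemerPresent(st, substring(rd, 1:m, 4:nchar(rd))))
  expect_identical(queryRead(st, rd), rep(TRUE, 4))
})
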