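---
title: "Buffered dynamic succinct de Bruijn graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Buffered dynamic succinct de Bruijn graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bufdbg)
```

## The model

The edge-centric de Bruijn graph of order $k$ over a set of reads has one
node per distinct $(k-1)$-mer (*nodemer*) and one edge per distinct $k$-mer
(*edgemer*): the edgemer $c_1 \dots c_k$ connects its prefix nodemer to its
suffix nodemer.  This package stores the graph as a Wheeler-graph index, a
generalization of the FM-index: nodes are arranged in the colexicographic
order of their labels (characters compared right to left, with a padding
symbol \$ that sorts before A), and the whole graph is represented by three
components,

* **ebwt** — the concatenation of the single-character edge labels, grouped
  by origin node in colexicographic order,
* **O** and **I** — the out- and indegree sequences in the same node order,
  each degree $d$ written in unary as $1\,0^d$,

plus rank/select support over these.  Because same-labeled edges preserve
the node order, following all $c$-labeled edges out of a contiguous node
interval lands in a contiguous node interval; every navigation operation
(node and edge search, out-label listing, in-label, out-edge rank, forward,
backward, in-edge interval) reduces to rank/select arithmetic on the three
components.  Node and edge ranks are 1-based throughout.

For the incoming-path property to hold everywhere — all length-$(k-1)$ paths
into a node spell its label — every nodemer with no predecessor edgemer
receives a chain of *dummy nodes* spelling its proper prefixes down to the
empty string $\varepsilon$.  Chains sharing prefixes are glued, so the
dummies form a tree rooted at $\varepsilon$.

## Making the static index dynamic

The index itself is never modified in place.  Two small dynamic structures
sit next to it:

* the **addition buffer** `HA`, an associative map from nodemer labels to a
  pair of bitsets: outgoing labels over ACGT and incoming labels over
  \$ACGT.  Buffering an edgemer sets the prefix nodemer's outgoing bit (its
  last character) and the suffix nodemer's incoming bit (its *first*
  character — the label of the incoming edge $k-2$ steps back in the
  Wheeler graph, not the edge's own label).  The \$ incoming bit records
  that a node needs (or has) an incoming dummy chain;
* the **deletion buffer** `BD`, one bit per colexicographic edge rank of
  the static index.

Queries see the modified edge set $E' = (E \cup A) \setminus D$.  The three
sets are kept disjoint by construction: re-adding a deleted edgemer only
clears its `BD` bit, deleting a buffered edgemer only clears its `HA` bits,
and deleting an absent edgemer is a warning-level no-op.  Traversal works
on *node tokens* — (static rank or absent, buffer entry or absent, label).
The label is carried explicitly: the pair alone could not re-probe the hash
map after a traversal step.  When a traversal step uses a buffer-only edge,
the destination may still be a static node, so its rank is recovered by
node search; leaving it absent would hide static out-edges from the rest of
the walk and break the equivalence between read traversal and independent
membership queries.

A read of length $m + k - 1$ is queried by traversal: after a positive
answer the next edgemer costs one token step instead of a fresh
$O(k)$-step search, so an in-graph read costs $O(m)$ elementary operations
rather than $O(km)$.  The package counts these operations (`navSteps()`)
and the test suite asserts the bound rather than wall-clock times, which
are hardware-dependent.

An optional per-node **mark vector** flags nodes whose label is a buffer
key or with an incident deleted edge, letting queries skip buffer lookups
on untouched nodes.  It is off by default and query results are asserted
to be bit-identical with and without it.

## Flushing the buffers

When the number of `HA` keys exceeds a fraction $t$ of the static edge
count (default $t = 0.025$; $t=0$ flushes immediately, $t=1$ essentially
never), the buffers are merged into a new static index in four phases:

1. **Dummy preparation** walks the deletion buffer: a node losing all its
   incoming edges without gaining a buffered one has its prefix chain
   recorded in `HA` (each prefix gets the outgoing bit toward the next
   character; chain members and the target get the \$ incoming bit).  The
   same treatment is applied to buffered nodemers with no incoming edge
   anywhere — a batch of novel edgemers otherwise produces sourceless
   nodes.  Chains are only added for nodes that keep at least one outgoing
   edge; a node with no surviving edge is not part of $E'$ at all.
2. **Merge planning** sorts the padded `HA` keys into the *buffer matrix*
   and interleaves them with the static node labels by $k-1$ rounds of
   partition refinement over the label columns, taken right to left.  The
   static label matrix is never materialized; its columns are produced by
   `prevColumn()`, which pushes each node's character along its out-edges
   (the root is forced to \$).  The result is a sequence of half-open
   interval pairs tiling both row ranges in order; after the last round a
   pair with both sides non-empty identifies one shared label.
3. **Merge execution** streams the pairs, emitting each node's outgoing
   label set and indegree: shared nodes combine the static edges (minus
   deletions) with the buffered bits, static-only nodes drop their deleted
   edges, buffer-only nodes come straight from their bitsets.  Two
   bookkeeping rules keep the output identical to a direct rebuild: a
   static-only node whose edges are all deleted is skipped (the root never
   is), and on a shared row that is a static dummy the buffered \$ bit is
   not counted again, because the parent dummy edge already exists — the
   case arises when a new chain glues onto the existing tree.
4. **Dummy cleanup** (on by default, switchable off) does a depth-first
   search of the dummy tree: a leaf dummy's edge to a full node is
   redundant when the node now has another incoming edge, or when the node
   has left the graph entirely (its only remaining edge is the dummy one
   and it has no outgoing edges); marks propagate bottom-up, and a final
   pass rewrites the index without the marked edges, dropping nodes left
   bare.  Without the second rule, deletions could leave chains dangling
   into nodes that no longer exist and the rebuilt index would differ from
   a direct build.

The central correctness property, asserted on hundreds of random update
scripts, is **rebuild equivalence**: flushing is bit-identical (ebwt, O, I)
to `buildIndex()` on the modified edgemer set.  This is only meaningful
with a canonical tie-break, so outgoing labels within a node are always
stored in ascending order (any order is admissible for correctness).

## Parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `k` | `buildIndex`, `cliBuild` | — | edgemer length, 2–32 (32 is the 2-bit packing limit of one 64-bit word; k = 2 is the smallest order with well-defined one-character nodemers) |
| `threshold` (`t`) | `BufBoss`, `flushIfNeeded` | 0.025 | flush when `HA` keys exceed `t * nEdges` (the practical sweet spot between update speed and buffer memory) |
| `rc` | `cliBuild`, `cliUpdate` | `TRUE` (CLI) | also process reverse complements, indexing both strands; the library-level `buildIndex` takes the edgemer set as given so that stranded fixtures stay reproducible |
| `useMark` | `BufBoss` | `FALSE` | maintain the mark accelerator |
| `cleanup` | `flushBuffers`, `cliUpdate` | `TRUE` | run the dummy cleanup phase |

Non-ACGT characters (N, IUPAC codes, gaps) split input sequences into
pieces; lowercase is accepted and upper-cased.  Splitting is the only
treatment of ambiguity codes that never fabricates edgemers, and it is
what comparable k-mer indexing tools do.

## Numerical and design choices

* Character codes A=0, C=1, G=2, T=3; with \$ < A the colexicographic and
  alphabetical orders coincide, and the byte order of the C locale sorts
  padded labels correctly.
* R has no 64-bit integers, so a packed k-mer is held as two exact 32-bit
  halves in doubles; all arithmetic stays below $2^{53}$.
* The root $\varepsilon$ is always materialized, even in fully cyclic
  graphs that need no dummies, so rank 1 is stable and an empty index (the
  result of building from nothing, or of deleting everything) is
  well-formed.
* `backward()` returns the smallest-rank predecessor (any is admissible).
* Rank/select uses plain prefix-sum and position arrays, and the ebwt keeps
  a per-character positional index instead of a wavelet tree.  At the
  problem sizes this package targets (in-memory graphs up to a few million
  edges) these are the simplest structures with the right contract;
  interval pairs are likewise stored as plain integer quadruples rather
  than the unary-coded differences a space-tight implementation would use.
* Serialization is a versioned little-endian container with magic bytes, a
  length manifest and a Fletcher-style checksum; a state file round-trips
  bit-exactly across platforms.

## What the synthetic data covers

`randomInstance()` draws a uniform random genome (default 300 bp), samples
reads from it with replacement, and produces interleaved add/delete
scripts whose additions are edgemers of short random sequences and whose
deletions are drawn from the evolving edge set.  This exercises every
structural case of the update algorithm — chain creation, gluing, chain
death, shared/boss-only/buffer-only merge rows — on graphs of up to a few
thousand nodes (genomes up to 500 bp, $k \in 2..8$, three hundred scripts
in the deepest suite; sizes chosen so the whole suite stays interactive).
It does **not** emulate sequencing error models, quality scores, coverage
biases or repeat structure of real genomes, so passing tests demonstrate
algorithmic correctness at small scale, not robustness to real-data
artifacts — membership answers on real reads are exact regardless, because
the index is lossless.

## Known limitations

* Pure R at desk scale: construction sorts in memory and navigation costs
  interpreted-loop constants.  The succinct layout is faithful, the
  constant factors of a C++ implementation are not.
* One static index plus one buffer generation; no hierarchy of indexes by
  subset size, and no merging of two independent static indexes.
* DNA alphabet only; no colors/annotations; the graph order $k$ is fixed at
  build time.
* Deletion of an edgemer leaves its nodemers in place while any incident
  edge survives; explicit node addition/deletion is intentionally
  unsupported (the node set is implied by the edge set).

## A worked example

```{r example}
reads <- exampleReads()
reads
st <- BufBoss(buildIndex(enumerateEdgemers(reads, k = 4), 4))
st
queryRead(st, "ACACGT")
up <- exampleUpdate()
st <- addEdgemers(st, enumerateEdgemers(up$add, 4))
st <- deleteEdgemers(st, up$delete)
st <- flushIfNeeded(st, force = TRUE)
nNodes(st); nEdges(st)
edgemerPresent(st, c("CGCA", "CGCG"))
```
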