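# bufdbg — buffered dynamic succinct de Bruijn graphs

De Bruijn graphs are the workhorse graph model of sequencing data: given
reads and an order *k*, every distinct *k*-mer (**edgemer**) becomes an
edge between its prefix and suffix (*k*−1)-mers (**nodemers**).  Succinct,
BWT-based representations of this graph (the BOSS family, a special case of
Wheeler-graph indexes) answer membership and traversal queries in tiny
space — but they are static, and consortium-scale collections keep growing
and shrinking.  `bufdbg` is for people who need a *k*-mer index they can
update: it keeps one static Wheeler index and makes it dynamic by
**buffering** updates instead of mutating bit vectors.

The index stores, over the node set arranged in colexicographic label order
(right-to-left comparison, with a left-padding symbol `$ < A < C < G < T`):

* `EBWT` — the concatenation of single-character edge labels grouped by
  origin node, ties broken by sorting labels within a node;
* `O`, `I` — outdegree/indegree sequences, each degree *d* encoded in unary
  as `1·0^d`;
* a dummy-node tree from the empty string ε so that every node has an
  incoming length-(*k*−1) path spelling its label.

All eight navigation operations (node/edge search, out-labels, in-label,
out-edge rank, forward, backward, in-edge interval) are rank/select
arithmetic on these components.  Dynamism comes from two buffers: an
**addition buffer** `HA` mapping nodemers to incoming/outgoing label
bitsets (incoming alphabet `$ACGT`, outgoing `ACGT`), and a **deletion
buffer** `BD` with one bit per colexicographic edge rank.  Queries see
`E′ = (E ∪ A) \ D` transparently; when `HA` grows past a fraction *t*
(default 0.025) of the indexed edges, a four-phase batched merge — dummy
preparation, partition-refinement merge planning, merge execution, dummy
cleanup — rebuilds the static index, bit-identically to building it from
`E′` directly.

## Worked example

The small graph used throughout the documentation: four strings, `k = 4`,
8 edgemers plus a 4-node dummy tree.

```r
library(bufdbg)
st <- BufBoss(buildIndex(enumerateEdgemers(exampleReads(), k = 4), 4))
st
#> BufBoss dynamic de Bruijn graph (k = 4 )
#>   static index: 13 nodes, 13 edges
#>   addition buffer: 0 nodemer entries
#>   deletion buffer: 0 marked edges
#>   flush threshold: 0.025

queryRead(st, "ACACGT")       # edgemers ACAC, CACG, ACGT, by traversal
#> [1] TRUE TRUE TRUE

up <- exampleUpdate()         # add edgemers of CGCACAGT; delete 3 edgemers
st <- addEdgemers(st, enumerateEdgemers(up$add, 4))
st <- deleteEdgemers(st, up$delete)
st <- flushIfNeeded(st, force = TRUE)
nNodes(st); nEdges(st)
#> [1] 14
#> [1] 13
edgemerPresent(st, c("CGCA", "CGCG"))
#> [1]  TRUE FALSE
```

The 13 nodes of the initial index are, in colexicographic order, ε, A,
ACA, CGA, GTA, AC, CAC, CGC, AG, ACG, GCG, AGT, CGT, with outdegrees
1,2,1,0,0,1,1,1,1,1,2,1,1 and indegrees 0,1,1,1,2,1,1,1,1,1,1,1,1; its
`EBWT` is `ACGCAGGTTACAA`.  After the update, the flushed index equals
`buildIndex()` of the modified 10-edgemer set bit for bit — including a new
dummy chain ε→G→GC for the node GCG, whose only incoming edge was deleted,
and removal of the chain through AC that became redundant.

A command-line wrapper over the same functions is installed at
`inst/scripts/bufdbg`:

```sh
bufdbg build -o graph.idx -k 31 reads.fastq.gz
bufdbg update graph.idx --add new.fa --del gone.fa -t 0.025
bufdbg query graph.idx queries.fa --mode read
```

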