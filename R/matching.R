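# Exact maximum-weight matching on small sparse multigraphs.
#
# The strong subgraph of a contracted partial graph has maximum degree
# floor(r/2) (a vertex carries total multiplicity r), so its components are
# tiny; an exact branch-and-bound over components is both simple and fast
# here, and is certified against brute-force enumeration in the tests.

# edges: data.frame/list with integer vectors v1, v2 (v1 < v2, no loops)
# and weight w.  Returns indices of the chosen edges.
.maxWeightMatching <- function(v1, v2, w) {
  ne <- length(v1)
  if (ne == 0L) return(integer(0))
  o <- order(v1, v2)
  v1 <- v1[o]; v2 <- v2[o]; w <- w[o]
  verts <- sort(unique(c(v1, v2)))
  # connected components over the edge set
  comp <- seq_along(verts)
  find <- function(i) { while (comp[i] != i) i <- comp[i] <- comp[comp[i]]; i }
  for (k in seq_len(ne)) {
    a <- find(match(v1[k], verts)); b <- find(match(v2[k], verts))
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_along(verts), find, integer(1))
  chosen <- integer(0)
  for (rt in unique(roots)) {
    inComp <- which(roots[match(v1, verts)] == rt)
    chosen <- c(chosen, inComp[.mwmComponent(v1[inComp], v2[inComp],
                                             w[inComp])])
  }
  sort(o[chosen])
}

# exact search within one component; returns positions of selected edges
.mwmComponent <- function(v1, v2, w) {
  ne <- length(v1)
  best <- list(weight = -1, sel = integer(0))
  # recursion over vertices in ascending order
  verts <- sort(unique(c(v1, v2)))
  vEdges <- lapply(verts, function(v) which(v1 == v | v2 == v))
  rec <- function(vi, used, sel, acc) {
    if (vi > length(verts)) {
      if (acc > best$weight) best <<- list(weight = acc, sel = sel)
      return(invisible(NULL))
    }
    # optimistic bound: half the weight of all edges still selectable
    free <- setdiff(seq_len(ne), sel)
    open <- free[!(v1[free] %in% used) & !(v2[free] %in% used)]
    if (acc + sum(w[open]) <= best$weight) return(invisible(NULL))
    v <- verts[vi]
    if (v %in% used) { rec(vi + 1L, used, sel, acc); return(invisible(NULL)) }
    for (k in vEdges[[vi]]) {
      if (v1[k] %in% used || v2[k] %in% used) next
      rec(vi + 1L, c(used, v1[k], v2[k]), c(sel, k), acc + w[k])
    }
    rec(vi + 1L, c(used, v), sel, acc)   # leave v unmatched
  }
  rec(1L, integer(0), integer(0), 0)
  best$sel
}
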