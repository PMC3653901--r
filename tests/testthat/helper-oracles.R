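# Independent oracles used to certify the implementation on tiny inputs.

# ---- breadth-first search over the DCJ operation graph -------------------
# States are uncapped partner vectors (0 = telomere).  The neighbour set is
# the full DCJ operation set: recombine two adjacencies (two rejoinings),
# an adjacency and a telomere (two rejoinings), join two telomeres, or cut
# one adjacency into two telomeres.

dcjNeighbors <- function(p) {
  exts <- seq_along(p)
  a1 <- exts[p > exts]
  pairs <- cbind(a1, p[a1])
  tel <- which(p == 0L)
  np <- nrow(pairs)
  res <- list()
  add <- function(p2) res[[length(res) + 1L]] <<- p2
  if (np >= 2L)
    for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
      a <- pairs[i, 1]; b <- pairs[i, 2]; c <- pairs[j, 1]; d <- pairs[j, 2]
      p2 <- p; p2[a] <- c; p2[c] <- a; p2[b] <- d; p2[d] <- b; add(p2)
      p2 <- p; p2[a] <- d; p2[d] <- a; p2[b] <- c; p2[c] <- b; add(p2)
    }
  for (i in seq_len(np)) for (t in tel) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    p2 <- p; p2[a] <- t; p2[t] <- a; p2[b] <- 0L; add(p2)
    p2 <- p; p2[b] <- t; p2[t] <- b; p2[a] <- 0L; add(p2)
  }
  if (length(tel) >= 2L)
    for (i in seq_len(length(tel) - 1L)) for (j in (i + 1L):length(tel)) {
      p2 <- p; p2[tel[i]] <- tel[j]; p2[tel[j]] <- tel[i]; add(p2)
    }
  for (i in seq_len(np)) {
    p2 <- p; p2[pairs[i, 1]] <- 0L; p2[pairs[i, 2]] <- 0L; add(p2)
  }
  res
}

bfsDcjDistance <- function(pa, pb, maxDepth = 8L) {
  keyOf <- function(p) paste(p, collapse = ",")
  target <- keyOf(pb)
  if (keyOf(pa) == target) return(0L)
  seen <- new.env(parent = emptyenv())
  assign(keyOf(pa), TRUE, envir = seen)
  frontier <- list(pa)
  for (depth in seq_len(maxDepth)) {
    nxt <- list()
    for (p in frontier)
      for (q in dcjNeighbors(p)) {
        k <- keyOf(q)
        if (k == target) return(depth)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    frontier <- nxt
    if (!length(frontier)) break
  }
  stop("BFS oracle: target not reached within maxDepth")
}

# uncapped partner vector of a genome, shared content
genomePartnerVec <- function(g, ref = g) {
  content <- DCJAliquot:::.contentTable(ref)
  DCJAliquot:::.genomePartners(g, DCJAliquot:::.contentKey(content))
}

# ---- exhaustive path-set enumeration -------------------------------------
# Mirrors the four path conditions: paths start/end black, alternate
# colours at matched interior vertices, joint edge usage bounded by the
# multiplicities, unmatched vertices interior to at most one path at most
# once, endpoints never interior, self-loops unusable.

enumAllPaths <- function(A, matched, u, v, maxLen) {
  out <- list()
  ne <- length(A$e1)
  rec <- function(cur, usage, eseq, interior) {
    for (k in seq_len(ne)) {
      if (usage[k] >= A$mult[k]) next
      if (A$e1[k] == A$e2[k]) next
      if (A$e1[k] == cur) nxt <- A$e2[k]
      else if (A$e2[k] == cur) nxt <- A$e1[k]
      else next
      col <- A$color[k]
      L <- length(eseq)
      if (L == 0L) {
        if (col != 0L) next
      } else if (cur %in% matched && A$color[eseq[L]] == col) next
      if (nxt == u) next
      if (nxt == v) {
        if (col == 0L) out[[length(out) + 1L]] <<- c(eseq, k)
        next
      }
      if (!(nxt %in% matched)) {
        if (nxt %in% interior) next
        newInterior <- c(interior, nxt)
      } else newInterior <- interior
      if (L + 1L < maxLen) {
        usage2 <- usage; usage2[k] <- usage2[k] + 1L
        rec(nxt, usage2, c(eseq, k), newInterior)
      }
    }
  }
  rec(u, integer(ne), integer(0), integer(0))
  out
}

pathInterior <- function(A, matched, u, eseq) {
  cur <- u
  vs <- integer(0)
  for (k in eseq) {
    cur <- if (A$e1[k] == cur) A$e2[k] else A$e1[k]
    vs <- c(vs, cur)
  }
  mid <- vs[-length(vs)]          # the arrival at v is never interior
  mid[!(mid %in% matched)]
}

# best (max count <= maxPaths, then min total length) over all multisets
oraclePathSet <- function(A, matched, u, v, maxPaths, maxLen = 10L) {
  maxLen <- min(maxLen, sum(A$mult))
  paths <- enumAllPaths(A, matched, u, v, maxLen + 1L)
  nP <- length(paths)
  if (!nP) return(c(np = 0L, total = 0L))
  plen <- vapply(paths, length, integer(1))
  pUse <- lapply(paths, function(es) tabulate(es, nbins = length(A$e1)))
  pInt <- lapply(paths, function(es) {
    it <- pathInterior(A, matched, u, es)
    it[!(it %in% matched)]
  })
  best <- c(np = 0L, total = 0L)
  rec <- function(i, count, totLen, usage, interior) {
    if (count > best["np"] ||
        (count == best["np"] && totLen < best["total"]))
      best <<- c(np = count, total = totLen)
    if (count == maxPaths || i > nP) return(invisible(NULL))
    for (j in i:nP) {
      if (any(usage + pUse[[j]] > A$mult)) next
      if (length(pInt[[j]]) &&
          (anyDuplicated(pInt[[j]]) || any(pInt[[j]] %in% interior))) next
      rec(j, count + 1L, totLen + plen[j], usage + pUse[[j]],
          c(interior, pInt[[j]]))
    }
  }
  rec(1L, 0L, 0L, integer(length(A$e1)), integer(0))
  best
}

# package result in the same (np, total length) form
packagePathSet <- function(A, matched, u, v, maxPaths) {
  paths <- DCJAliquot:::.findPathsRaw(A, matched, u, v, maxPaths)
  msg <- DCJAliquot:::.validatePathsRaw(A, matched, u, v, paths)
  if (!isTRUE(msg)) stop("returned path set invalid: ", msg)
  c(np = length(paths),
    total = sum(vapply(paths, function(p) p$len, integer(1))))
}

randomPathGraph <- function(maxV = 8L) {
  V <- sample(4:maxV, 1L)
  verts <- seq_len(V)
  ne <- sample(3:(V + 3L), 1L)
  e1 <- integer(0); e2 <- integer(0); color <- integer(0); mult <- integer(0)
  for (k in seq_len(ne)) {
    ab <- sort(sample(verts, 2L))
    e1 <- c(e1, ab[1]); e2 <- c(e2, ab[2])
    color <- c(color, sample(c(0L, 0L, 0L, 1L), 1L))
    mult <- c(mult, sample(1:3, 1L))
  }
  matched <- sample(verts, sample(0:(V %/% 2L), 1L))
  list(A = list(e1 = e1, e2 = e2, color = color, mult = mult,
                prov = vector("list", ne)),
       matched = matched, u = 1L, v = 2L)
}

# ---- brute-force maximum weight matching ---------------------------------
bruteMaxWeightMatching <- function(v1, v2, w) {
  ne <- length(v1)
  best <- 0
  for (mask in 0:(2^ne - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(ne) - 1L)) > 0L)
    vs <- c(v1[sel], v2[sel])
    if (anyDuplicated(vs)) next
    best <- max(best, sum(w[sel]))
  }
  best
}

# ---- exhaustive genome-halving (r = 2) oracle ----------------------------

permutationsOf <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in permutationsOf(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

# all candidate perfectly duplicated partner vectors for n families, r = 2
allHalvedPartnerVectors <- function(n) {
  cands <- list()
  seen <- new.env(parent = emptyenv())
  for (perm in permutationsOf(seq_len(n)))
    for (signMask in 0:(2^n - 1L)) {
      sgn <- ifelse(bitwAnd(signMask, 2^(seq_len(n) - 1L)) > 0L, -1L, 1L)
      seqv <- sgn * perm
      for (cutMask in 0:(2^(n - 1L) - 1L)) {
        cuts <- which(bitwAnd(cutMask, 2^(seq_len(max(0L, n - 1L)) - 1L)) > 0L)
        bounds <- c(0L, cuts, n)
        chroms <- lapply(seq_len(length(bounds) - 1L), function(i)
          seqv[(bounds[i] + 1L):bounds[i + 1L]])
        qkey <- paste(vapply(chroms, function(ch)
          DCJAliquot:::.canonicalSeq(ch, FALSE), character(1)) |> sort(),
          collapse = " / ")
        if (!is.null(seen[[qkey]])) next
        seen[[qkey]] <- TRUE
        for (assignMask in 0:(2^n - 1L)) {
          cp1 <- ifelse(bitwAnd(assignMask, 2^(seq_len(n) - 1L)) > 0L, 2L, 1L)
          p <- integer(4L * n)   # slots: family f copy c -> (f-1)*2 + c
          link <- function(a, b) { p[a] <<- b; p[b] <<- a }
          for (grp in 1:2)
            for (ch in chroms) {
              fams <- abs(ch); sgns <- sign(ch)
              cps <- if (grp == 1L) cp1[fams] else 3L - cp1[fams]
              slots <- (fams - 1L) * 2L + cps
              ent <- ifelse(sgns > 0L, 2L * slots - 1L, 2L * slots)
              ext <- ifelse(sgns > 0L, 2L * slots, 2L * slots - 1L)
              L <- length(fams)
              if (L > 1L) for (i in seq_len(L - 1L)) link(ext[i], ent[i + 1L])
            }
          cands[[length(cands) + 1L]] <- p
        }
      }
    }
  cands
}

oracleAliquotMin <- function(gobs, cands) {
  pObs <- genomePartnerVec(gobs)
  min(vapply(cands, function(p)
    DCJAliquot:::.dcjDistancePartners(pObs, p), integer(1)))
}
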