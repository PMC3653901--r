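# The aliquoting heuristic: strong-adjacency inference by maximum-weight
# matching, weak-adjacency inference by N_p/C_p pair scoring, and
# linearization of circular chromosomes.
#
# Internal state (an environment):
#   n, r        families and duplicated size (families/copies renumbered
#               1..n / 1..r; original labels kept for the output)
#   bp          capped partner vector over labelled extremities; non-cap
#               extremity of family f, copy c: tail ((f-1)r+c-1)*2+1, head
#               +2; caps above capBase = 2rn; NA = consumed
#   pObs        uncapped partner vector of G_obs (0 = telomere)
#   H           list of two-column matrices of inferred adjacencies
#   matchedOnce logical over family-extremity ids 1..2n

.feOf <- function(idx, st) {
  out <- integer(length(idx))
  cap <- idx > st$capBase
  q <- (idx[!cap] - 1L) %/% 2L
  fam <- q %/% st$r + 1L
  out[!cap] <- 2L * (fam - 1L) + ((idx[!cap] - 1L) %% 2L) + 1L
  out
}

.copyOf <- function(idx, st) {
  ifelse(idx > st$capBase, idx - st$capBase,
         ((idx - 1L) %/% 2L) %% st$r + 1L)
}

# labelled extremity index of (family-extremity fe, copy c)
.extOf <- function(fe, cp, st) {
  ifelse(fe == 0L, st$capBase + cp,
         (((fe + 1L) %/% 2L - 1L) * st$r + cp - 1L) * 2L +
           2L - fe %% 2L)
}

.initAliquotState <- function(gobs, r) {
  fs <- familySizes(gobs)
  if (!length(fs)) stop("empty genome")
  if (length(unique(fs)) != 1L)
    stop("not a rearranged duplicated genome: family sizes are not uniform")
  if (fs[1] != r)
    stop("family sizes (", fs[1], ") differ from the requested duplicated size ", r)
  if (r < 2L) stop("duplicated size r must be >= 2")
  content <- .contentTable(gobs)
  key <- .contentKey(content)
  n <- length(unique(content$family))
  N2 <- 2L * r * n
  st <- new.env(parent = emptyenv())
  st$n <- n; st$r <- as.integer(r); st$capBase <- N2
  st$content <- content
  st$pObs <- .genomePartners(gobs, key)
  # capped partner vector: a fresh cap pair per linear chromosome
  bp <- st$pObs
  capN <- 0L
  tel <- which(bp == 0L)
  # pair telomeres chromosome-wise: walk chromosomes of gobs in order
  for (ch in gobs@chromosomes) {
    if (ch$circular || length(ch$family) == 0L) next
    s <- .chromSlots(ch, key)
    e1 <- .entryExt(s[1], ch$sign[1])
    e2 <- .exitExt(s[length(s)], ch$sign[length(ch$sign)])
    bp <- c(bp, e1, e2)
    bp[e1] <- N2 + capN + 1L
    bp[e2] <- N2 + capN + 2L
    capN <- capN + 2L
  }
  stopifnot(all(bp[tel] > N2))
  st$bp <- bp
  st$H <- list()
  st$matchedOnce <- logical(2L * n)
  st$gobsName <- gobs@name
  # union-find over family extremities tracking the connectivity of the
  # growing reconstruction (co-extremities of one family start connected);
  # a candidate pair inside one component would close a circular chromosome
  st$uf <- seq_len(2L * n)
  for (f in seq_len(n)) .ufUnion(st, 2L * f - 1L, 2L * f)
  st
}

.ufFind <- function(st, x) {
  r <- x
  while (st$uf[r] != r) r <- st$uf[r]
  while (st$uf[x] != r) { nx <- st$uf[x]; st$uf[x] <- r; x <- nx }
  r
}

.ufUnion <- function(st, a, b) {
  ra <- .ufFind(st, a); rb <- .ufFind(st, b)
  if (ra != rb) st$uf[ra] <- rb
  invisible(NULL)
}

.closesCircle <- function(st, u, v) {
  if (u == 0L || v == 0L) return(FALSE)
  .ufFind(st, u) == .ufFind(st, v)
}

# contracted partial graph of the current graph B (black edges only)
.stateContract <- function(st) {
  alive <- which(!is.na(st$bp))
  x <- alive[st$bp[alive] > alive]
  y <- st$bp[x]
  fe1 <- .feOf(x, st); fe2 <- .feOf(y, st)
  c1 <- .copyOf(x, st); c2 <- .copyOf(y, st)
  swap <- fe1 > fe2 | (fe1 == fe2 & c1 > c2)
  tmp <- fe1[swap]; fe1[swap] <- fe2[swap]; fe2[swap] <- tmp
  tmp <- c1[swap]; c1[swap] <- c2[swap]; c2[swap] <- tmp
  o <- order(fe1, fe2, c1, c2)
  fe1 <- fe1[o]; fe2 <- fe2[o]; c1 <- c1[o]; c2 <- c2[o]
  keyv <- fe1 * (2L * st$n + 2L) + fe2
  first <- which(!duplicated(keyv))
  mult <- diff(c(first, length(keyv) + 1L))
  prov <- vector("list", length(first))
  for (i in seq_along(first)) {
    ix <- first[i]:(first[i] + mult[i] - 1L)
    prov[[i]] <- cbind(c1[ix], c2[ix])
  }
  list(e1 = fe1[first], e2 = fe2[first],
       color = integer(length(first)),
       mult = as.integer(mult), prov = prov)
}

.step1Matching <- function(A, st) {
  strong <- which(A$mult > 1L & A$e1 != A$e2)
  if (!length(strong)) return(NULL)
  # a strong edge that would close a circular chromosome contradicts the
  # adjacencies already accepted into the reconstruction; hold it back so
  # the evidence can resolve through paths instead (such vertices are
  # still matched later, by a rebuilt matching or by weak inference)
  closes <- vapply(strong, function(k)
    .closesCircle(st, A$e1[k], A$e2[k]), logical(1))
  if (any(!closes)) strong <- strong[!closes]
  sel <- .maxWeightMatching(A$e1[strong], A$e2[strong], A$mult[strong])
  if (!length(sel)) return(NULL)
  k <- strong[sel]
  ord <- order(-A$mult[k], A$e1[k], A$e2[k])
  cbind(A$e1[k][ord], A$e2[k][ord])
}

# append the pending matched pairs' gray edges (multiplicity r) to A
.withGrayEdges <- function(A, pending, r) {
  for (i in seq_len(nrow(pending))) {
    a <- min(pending[i, ]); b <- max(pending[i, ])
    A$e1 <- c(A$e1, a); A$e2 <- c(A$e2, b)
    A$color <- c(A$color, 1L)
    A$mult <- c(A$mult, r)
    A$prov <- c(A$prov, list(NULL))
  }
  A
}

# pick the lowest available provenance unit of edge k seen from vertex `at`
.pickUnit <- function(A, k, at, availAt, availOther = NULL) {
  pv <- A$prov[[k]]
  atFirst <- A$e1[k] == at
  cAt <- if (atFirst) pv[, 1] else pv[, 2]
  cOth <- if (atFirst) pv[, 2] else pv[, 1]
  ok <- availAt(cAt)
  if (!is.null(availOther)) ok <- ok & availOther(cOth)
  cand <- which(ok)
  if (!length(cand)) stop("internal error: no available provenance unit")
  cand <- cand[order(cAt[cand], cOth[cand])][1]
  c(at = cAt[cand], other = cOth[cand])
}

# Process one matched pair (u, v): find paths, derive the r inferred
# adjacencies (u_i, v_j), contract them into graph B, record them in H.
# v may be the cap vertex (0); u never is.  `pending` holds the matched
# pairs not yet processed (including this one).
.processMatchedPair <- function(st, u, v, pending) {
  r <- st$r
  A <- .withGrayEdges(.stateContract(st), pending, r)
  matchedIds <- unique(as.vector(pending))
  paths <- .findPathsRaw(A, matchedIds, u, v, r)
  lens <- vapply(paths, function(p) p$len, integer(1))
  oddIdx <- which(lens %% 2L == 1L)
  evenIdx <- which(lens %% 2L == 0L)
  if (length(evenIdx) %% 2L == 1L) {
    # an unpaired even path cannot be crossed with a partner; keeping its
    # own terminal copies as the inferred adjacency still realises its
    # black cycle, which beats pairing those copies blindly
    oddIdx <- c(oddIdx, evenIdx[length(evenIdx)])
    evenIdx <- evenIdx[-length(evenIdx)]
  }
  usedU <- logical(r)
  usedVcap <- integer(0)            # cap copy numbers consumed this round
  usedV <- logical(r)
  availU <- function(cp) !usedU[cp]
  availV <- if (v == 0L) {
    function(cp) !(cp %in% usedVcap) }
  else {
    function(cp) !usedV[cp]
  }
  markV <- function(cp) {
    if (v == 0L) usedVcap <<- c(usedVcap, cp) else usedV[cp] <<- TRUE
  }
  termU <- termV <- rep(NA_integer_, length(paths))
  for (i in c(oddIdx, evenIdx)) {
    p <- paths[[i]]
    if (p$len == 1L) {
      unit <- .pickUnit(A, p$eidx[1], u, availU, availV)
      termU[i] <- unit["at"]; termV[i] <- unit["other"]
    } else {
      unit <- .pickUnit(A, p$eidx[1], u, availU)
      termU[i] <- unit["at"]
      kLast <- p$eidx[p$len]
      unit <- .pickUnit(A, kLast, v, availV)
      termV[i] <- unit["at"]
    }
    usedU[termU[i]] <- TRUE
    markV(termV[i])
  }
  gray <- matrix(integer(0), 0L, 2L)
  for (i in oddIdx)
    gray <- rbind(gray, c(termU[i], termV[i]))
  if (length(evenIdx))
    for (j in seq(1L, length(evenIdx), by = 2L)) {
      p <- evenIdx[j]; q <- evenIdx[j + 1L]
      gray <- rbind(gray, c(termU[p], termV[q]), c(termU[q], termV[p]))
    }
  # leftover gray units: pair remaining free copies by ascending copy ID
  freeU <- which(!usedU)
  if (v == 0L) {
    for (cu in freeU) {
      aliveCaps <- which(!is.na(st$bp)) ; aliveCaps <- aliveCaps[aliveCaps > st$capBase]
      freeCaps <- setdiff(aliveCaps - st$capBase, usedVcap)
      if (!length(freeCaps)) {
        # spawn a null-chromosome cap pair so the contraction stays uniform
        st$bp <- c(st$bp, length(st$bp) + 2L, length(st$bp) + 1L)
        freeCaps <- length(st$bp) - 1L - st$capBase
      }
      cv <- min(freeCaps)
      usedVcap <- c(usedVcap, cv)
      gray <- rbind(gray, c(cu, cv))
    }
  } else {
    freeV <- which(!usedV)
    stopifnot(length(freeU) == length(freeV))
    # pair remaining copies so that the contracted black edge lands on the
    # best-supported family adjacency (falling back to ascending copy IDs)
    edgeMult <- new.env(parent = emptyenv())
    for (k in seq_along(A$e1))
      if (A$color[k] == 0L)
        assign(paste(A$e1[k], A$e2[k]), A$mult[k], envir = edgeMult)
    support <- function(cu, cv) {
      pu <- st$bp[.extOf(u, cu, st)]; pv <- st$bp[.extOf(v, cv, st)]
      a <- .feOf(pu, st); b <- .feOf(pv, st)
      key <- paste(min(a, b), max(a, b))
      m <- edgeMult[[key]]
      if (is.null(m)) 0L else m
    }
    for (cu in freeU) {
      sc <- vapply(freeV, function(cv) support(cu, cv), integer(1))
      cv <- freeV[order(-sc, freeV)][1]
      gray <- rbind(gray, c(cu, cv))
      freeV <- setdiff(freeV, cv)
    }
  }
  # to labelled extremities
  grayExt <- cbind(.extOf(rep(u, nrow(gray)), gray[, 1], st),
                   .extOf(rep(v, nrow(gray)), gray[, 2], st))
  st$H[[length(st$H) + 1L]] <- grayExt
  # contract each inferred edge with its two incident black edges
  for (i in seq_len(nrow(grayExt))) {
    x <- grayExt[i, 1]; y <- grayExt[i, 2]
    px <- st$bp[x]; py <- st$bp[y]
    if (px == y) {
      st$bp[x] <- NA_integer_; st$bp[y] <- NA_integer_
    } else {
      st$bp[px] <- py; st$bp[py] <- px
      st$bp[x] <- NA_integer_; st$bp[y] <- NA_integer_
    }
  }
  for (fe in c(u, v)) {
    if (fe == 0L) next
    if (st$matchedOnce[fe])
      stop("internal error: vertex matched twice")
    st$matchedOnce[fe] <- TRUE
  }
  if (v != 0L) .ufUnion(st, u, v)
  # all copies of the removed vertices must be consumed
  copies <- .extOf(rep(u, r), seq_len(r), st)
  stopifnot(all(is.na(st$bp[copies])))
  invisible(st)
}

# candidate pairs within graph-A distance <= d (self-loops ignored)
.pairsWithin <- function(A, d) {
  nl <- A$e1 != A$e2
  if (!any(nl)) return(matrix(integer(0), 0L, 2L))
  e1 <- A$e1[nl]; e2 <- A$e2[nl]
  pairs <- unique(cbind(e1, e2))
  if (d > 1L) {
    verts <- sort(unique(c(e1, e2)))
    nb <- lapply(verts, function(v) unique(c(e2[e1 == v], e1[e2 == v])))
    names(nb) <- verts
    for (s in verts) {
      reach <- s; frontier <- s
      for (step in seq_len(d)) {
        frontier <- setdiff(unique(unlist(nb[as.character(frontier)])), reach)
        if (!length(frontier)) break
        reach <- c(reach, frontier)
      }
      reach <- setdiff(reach, s)
      good <- reach[reach > s]
      if (length(good))
        pairs <- rbind(pairs, cbind(rep(s, length(good)), good))
    }
    pairs <- unique(pairs)
  }
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# choose the weak pair with the highest W_p = alpha*N_p + (1-alpha)*C_p
#
# Path sets never leave a connected component of graph A, so a pair's
# score can only change when its component changes; scores are cached per
# pair against an exact textual signature of the component's edge set and
# recomputed only on signature mismatch.
.step2Choose <- function(st, depth, alpha, tieRev = FALSE) {
  A <- .stateContract(st)
  if (!length(A$e1)) return(NULL)
  if (is.null(st$s2cache)) st$s2cache <- new.env(parent = emptyenv())
  # components of A (over all edges, self-loops included)
  verts0 <- sort(unique(c(A$e1, A$e2)))
  comp <- seq_along(verts0)
  find <- function(i) { while (comp[i] != i) i <- comp[i] <- comp[comp[i]]; i }
  for (k in seq_along(A$e1)) {
    a <- find(match(A$e1[k], verts0)); b <- find(match(A$e2[k], verts0))
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_along(verts0), find, integer(1))
  edgeComp <- roots[match(A$e1, verts0)]
  sigs <- vapply(split(seq_along(A$e1), edgeComp), function(ix)
    paste(A$e1[ix], A$e2[ix], A$mult[ix], collapse = ";"), character(1))
  vertSig <- setNames(sigs[as.character(roots)], verts0)
  for (d in c(depth, depth + 1L)) {
    pairs <- .pairsWithin(A, d)
    if (!nrow(pairs)) next
    keys <- paste0(d, "|", pairs[, 1], "|", pairs[, 2])
    sigOf <- vertSig[as.character(pairs[, 1])]
    stats <- matrix(NA_integer_, nrow(pairs), 3L)
    miss <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      hit <- st$s2cache[[keys[i]]]
      if (!is.null(hit) && identical(hit$sig, sigOf[[i]]))
        stats[i, ] <- hit$stats
      else miss[i] <- TRUE
    }
    if (any(miss)) {
      verts <- sort(unique(c(A$e1, A$e2, as.vector(pairs))))
      edges <- cbind(match(A$e1, verts) - 1L, match(A$e2, verts) - 1L,
                     A$color, A$mult)
      fresh <- score_pair_stats(edges, logical(length(verts)),
                                cbind(match(pairs[miss, 1], verts) - 1L,
                                      match(pairs[miss, 2], verts) - 1L),
                                st$r)
      stats[miss, ] <- fresh
      mi <- which(miss)
      for (j in seq_along(mi))
        st$s2cache[[keys[mi[j]]]] <-
          list(stats = fresh[j, ], sig = sigOf[[mi[j]]])
    }
    np <- stats[, 1]; S <- stats[, 2]; L <- stats[, 3]
    ok <- np >= 1L
    if (!any(ok)) next
    W <- ifelse(ok, alpha * np + (1 - alpha) * ifelse(L > 0, S / L, 0), -Inf)
    # pairs that would close a circular chromosome contradict the accepted
    # adjacencies and are held back unless nothing else scores; ties on
    # W_p prefer gene-gene pairs over telomere (cap) pairs, then the
    # lexicographically smallest pair (candidates are pre-sorted)
    closes <- vapply(seq_len(nrow(pairs)), function(i)
      .closesCircle(st, pairs[i, 1], pairs[i, 2]), logical(1))
    pool <- if (any(ok & !closes)) which(ok & !closes) else which(ok)
    tied <- pool[W[pool] >= max(W[pool]) - 1e-9]
    hasCap <- pairs[tied, 1] == 0L | pairs[tied, 2] == 0L
    ord <- tied[order(hasCap)]
    # the reversed orientation explores the opposite end of every tie;
    # aliquot() runs both and keeps the more parsimonious reconstruction
    best <- if (tieRev) ord[length(ord)] else ord[1]
    return(pairs[best, ])
  }
  NULL
}

.aliveNonCap <- function(st) {
  alive <- which(!is.na(st$bp))
  alive[alive <= st$capBase]
}

#' Reconstruct a perfectly duplicated ancestor (genome aliquoting)
#'
#' Given a rearranged duplicated genome \code{gobs} of duplicated size
#' \code{r}, reconstructs a perfectly duplicated genome \code{G_dup}
#' heuristically minimising the DCJ distance to \code{gobs}, together with
#' its single-copy quotient \code{G_anc}.  The heuristic iterates
#' strong-adjacency inference (maximum-weight matching over edges of
#' multiplicity > 1 in the contracted partial graph, with disjoint-path
#' search assigning gene copies) and weak-adjacency inference (one pair per
#' round, chosen by the combined weight \eqn{W_p}), then linearises any
#' circular chromosomes by DCJ merges/splits that do not increase the
#' distance whenever possible.
#'
#' @param gobs a \code{\linkS4class{Genome}} in which every family has size
#'   exactly \code{r}.
#' @param r duplicated size (>= 2).
#' @param alpha mixing weight of the pair score (default 0.5).
#' @param depth maximum graph distance between candidate pairs scored during
#'   weak-adjacency inference (default 1).
#' @return an \code{\linkS4class{AliquotResult}}.
#' @examples
#' anc <- Genome(list(1:5), name = "anc")
#' obs <- applyRandomDcj(wgd(anc, 3), 4)
#' res <- aliquot(obs, 3)
#' res@distance
#' @export
aliquot <- function(gobs, r, alpha = 0.5, depth = 1L) {
  stopifnot(is(gobs, "Genome"))
  depth <- as.integer(depth)
  # the greedy's score ties are broken deterministically; both tie
  # orientations are explored and the more parsimonious reconstruction
  # (smaller inferred distance; ties favour the ascending orientation) kept
  runA <- .aliquotPipeline(gobs, r, alpha, depth, tieRev = FALSE)
  runB <- .aliquotPipeline(gobs, r, alpha, depth, tieRev = TRUE)
  run <- if (runB$D < runA$D) runB else runA
  st <- run$st; pH <- run$pH
  gdup <- .partnersToGenome(st, pH, paste0(st$gobsName, "_dup"))
  if (!isPerfectlyDuplicated(gdup, st$r))
    stop("internal error: reconstruction is not perfectly duplicated")
  ganc <- quotientGenome(gdup, st$r)
  ganc@name <- paste0(st$gobsName, "_anc")
  new("AliquotResult", gdup = gdup, ganc = ganc,
      distance = as.numeric(run$D),
      relativeDistance = run$D / (st$r * st$n),
      r = st$r, alpha = alpha, depth = depth)
}

.aliquotPipeline <- function(gobs, r, alpha, depth, tieRev) {
  st <- .initAliquotState(gobs, as.integer(r))
  guard <- 0L
  while (length(.aliveNonCap(st))) {
    if ((guard <- guard + 1L) > 8L * st$n + 16L)
      stop("internal error: aliquoting did not converge")
    A <- .stateContract(st)
    pairs <- .step1Matching(A, st)
    if (!is.null(pairs)) {
      # a pair may become circle-closing through the contractions of the
      # pairs processed before it; defer such pairs to the next round's
      # rebuilt matching unless that would stall the round entirely
      deferred <- logical(nrow(pairs))
      progressed <- FALSE
      for (i in seq_len(nrow(pairs))) {
        uv <- pairs[i, ]
        if (uv[1] == 0L) uv <- uv[2:1]
        if (.closesCircle(st, uv[1], uv[2])) { deferred[i] <- TRUE; next }
        pending <- pairs[c(i, which(seq_len(nrow(pairs)) > i &
                                      !deferred[seq_len(nrow(pairs))])), ,
                         drop = FALSE]
        .processMatchedPair(st, uv[1], uv[2], pending)
        progressed <- TRUE
      }
      if (!progressed)
        for (i in which(deferred)) {
          uv <- pairs[i, ]
          if (uv[1] == 0L) uv <- uv[2:1]
          .processMatchedPair(st, uv[1], uv[2],
                              pairs[i, , drop = FALSE])
        }
      next
    }
    ch <- .step2Choose(st, depth, alpha, tieRev)
    if (!is.null(ch)) {
      if (ch[1] == 0L) ch <- ch[2:1]
      .processMatchedPair(st, ch[1], ch[2], matrix(ch, 1L))
      next
    }
    # No scored candidate anywhere: the remaining vertices carry only
    # self-loop evidence (any other incident edge would have made them
    # scoreable).  Pairing two such vertices closes their self-loops into
    # an alternating cycle, which beats telomere pairing; the odd one out
    # is paired with the cap.  Lowest IDs first.
    remaining <- sort(unique(.feOf(.aliveNonCap(st), st)))
    while (length(remaining) >= 2L) {
      u <- remaining[1]
      cand <- remaining[-1]
      open <- cand[!vapply(cand, function(v) .closesCircle(st, u, v),
                           logical(1))]
      v <- if (length(open)) open[1] else cand[1]
      .processMatchedPair(st, u, v, matrix(c(u, v), 1L))
      remaining <- setdiff(remaining, c(u, v))
    }
    if (length(remaining))
      .processMatchedPair(st, remaining[1], 0L, matrix(c(remaining[1], 0L), 1L))
  }
  pH <- .finalizeH(st)
  pH <- .refineCopyLabels(st, pH)
  pH <- .linearizeCircular(st, pH)
  pH <- .refineCopyLabels(st, pH)
  # family-level moves and copy relabels unlock each other; iterate to a
  # joint fixpoint (distance strictly decreases, so this terminates)
  repeat {
    D0 <- .dcjDistancePartners(st$pObs, pH)
    pH <- .localSearchQuotient(st, pH)
    pH <- .refineCopyLabels(st, pH)
    if (.dcjDistancePartners(st$pObs, pH) >= D0) break
  }
  list(st = st, pH = pH, D = .dcjDistancePartners(st$pObs, pH))
}

# ---- H finalisation ------------------------------------------------------

# Collapse the inferred adjacency list H into an uncapped partner vector
# (0 = telomere).  H is an r-fold cover of a single-copy quotient genome;
# Step 3 turns every circular component into linear chromosomes, after
# which the cover always splits into r identical copies.
.finalizeH <- function(st) {
  H <- do.call(rbind, st$H)
  pH <- integer(st$capBase)
  for (i in seq_len(nrow(H))) {
    x <- H[i, 1]; y <- H[i, 2]
    if (y > st$capBase || x > st$capBase) {
      e <- if (x > st$capBase) y else x
      pH[e] <- 0L
    } else {
      pH[x] <- y; pH[y] <- x
    }
  }
  pH
}

# ordered family walks of the quotient chromosomes implied by pH
.quotientFamilyWalks <- function(st, pH) {
  n <- st$n
  qp <- integer(2L * n)
  for (fe in seq_len(2L * n)) {
    p <- pH[.extOf(fe, 1L, st)]
    qp[fe] <- if (p == 0L) 0L else .feOf(p, st)
  }
  cofe <- function(fe) fe + if (fe %% 2L == 1L) 1L else -1L
  visited <- logical(2L * n)
  walks <- list()
  for (s in which(qp == 0L)) {
    if (visited[s]) next
    fams <- integer(0)
    e <- s
    repeat {
      visited[e] <- TRUE
      e2 <- cofe(e)
      visited[e2] <- TRUE
      fams <- c(fams, (e + 1L) %/% 2L)
      nxt <- qp[e2]
      if (nxt == 0L) break
      e <- nxt
    }
    walks[[length(walks) + 1L]] <- list(fams = fams, circular = FALSE)
  }
  for (s in seq_len(2L * n)) {
    if (visited[s]) next
    fams <- integer(0)
    e <- s
    repeat {
      visited[e] <- TRUE
      e2 <- cofe(e)
      visited[e2] <- TRUE
      fams <- c(fams, (e + 1L) %/% 2L)
      e <- qp[e2]
      if (e == s) break
    }
    walks[[length(walks) + 1L]] <- list(fams = fams, circular = TRUE)
  }
  walks
}

# Copy-ID refinement: copy subscripts are arbitrary labels, but the labelled
# DCJ distance to G_obs depends on them.  Relabelling the copies of a
# contiguous segment of quotient families (conjugating the partner vector
# by the product of their copy transpositions) leaves the unlabelled
# reconstruction, its perfect duplication and its linearity untouched, so a
# greedy sweep over all segments and copy pairs accepting strict
# improvements is a safe refinement of the bookkeeping.  Relabelling never
# changes the quotient, so the family walks stay valid throughout.
.refineCopyLabels <- function(st, pH) {
  walks <- .quotientFamilyWalks(st, pH)
  if (!length(walks)) return(pH)
  refine_copy_labels_cpp(st$pObs, pH, st$r, walks)
}

# ---- Step 3: linearise circular chromosomes ------------------------------
#
# Operations act on the family level of the quotient genome: a family
# adjacency has exactly r concrete occurrences in H (one per copy), and a
# DCJ applied to all r occurrences at once (against the r occurrences of a
# target adjacency of a linear component, or cutting all r into telomeres)
# always leaves an r-fold cover whose linear part splits into r identical
# chromosomes -- even when a circular component is a "wound" cover (fewer
# than r physical circles winding around the quotient cycle).

# family-level components of the quotient genome implied by pH
.familyComponents <- function(st, pH) {
  n <- st$n
  qp <- integer(2L * n)
  for (fe in seq_len(2L * n)) {
    p <- pH[.extOf(fe, 1L, st)]
    qp[fe] <- if (p == 0L) 0L else .feOf(p, st)
  }
  cofe <- function(fe) fe + if (fe %% 2L == 1L) 1L else -1L
  comps <- list()
  visited <- logical(2L * n)
  for (s in seq_len(2L * n)) {
    if (visited[s]) next
    fes <- integer(0)
    stack <- s
    telo <- FALSE
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (visited[cur]) next
      visited[cur] <- TRUE
      fes <- c(fes, cur)
      if (qp[cur] == 0L) telo <- TRUE else stack <- c(stack, qp[cur])
      stack <- c(stack, cofe(cur))
    }
    fes <- sort(fes)
    adjs <- unique(t(vapply(fes, function(fe)
      sort(c(fe, qp[fe])), integer(2))))
    adjs <- adjs[order(adjs[, 1], adjs[, 2]), , drop = FALSE]
    comps[[length(comps) + 1L]] <-
      list(fes = fes, adjs = adjs, circular = !telo)
  }
  comps[order(vapply(comps, function(cp) cp$fes[1], integer(1)))]
}

# the r concrete occurrences of family adjacency (fa, fb), fa > 0, sorted
# by the fa-side copy; fb == 0 yields the r telomere occurrences (e, 0)
.adjOccurrences <- function(st, pH, fa, fb) {
  xs <- .extOf(rep(fa, st$r), seq_len(st$r), st)
  if (fb == 0L) return(lapply(xs, function(x) c(x, 0L)))
  lapply(xs, function(x) c(x, pH[x]))
}

.applyGroupDcj <- function(pH, circAdj, tgtAdj, type) {
  # circAdj/tgtAdj: lists over copies of concrete adjacencies (a, b)/(c, d);
  # a zero member marks a telomere.  type 0 joins a-c & b-d, type 1 joins
  # a-d & b-c; joining an extremity with a telomere slot leaves it telomeric.
  for (k in seq_along(circAdj)) {
    a <- circAdj[[k]][1]; b <- circAdj[[k]][2]
    c_ <- tgtAdj[[k]][1]; d_ <- tgtAdj[[k]][2]
    if (type == 0L) { j1 <- c(a, c_); j2 <- c(b, d_) }
    else            { j1 <- c(a, d_); j2 <- c(b, c_) }
    for (j in list(j1, j2)) {
      if (j[1] > 0L && j[2] > 0L) { pH[j[1]] <- j[2]; pH[j[2]] <- j[1] }
      else if (j[1] > 0L) pH[j[1]] <- 0L
      else if (j[2] > 0L) pH[j[2]] <- 0L
    }
  }
  pH
}

# a circular quotient component is a separated cover when its copy-level
# realisation consists of r disjoint circles (trivial monodromy)
.isSeparatedCover <- function(st, pH, comp) {
  exts <- as.vector(vapply(comp$fes, function(fe)
    .extOf(rep(fe, st$r), seq_len(st$r), st), integer(st$r)))
  seen <- logical(max(exts))
  circles <- 0L
  cofeExt <- function(e) e + if (e %% 2L == 1L) 1L else -1L
  for (s in exts) {
    if (seen[s]) next
    circles <- circles + 1L
    e <- s
    repeat {
      seen[e] <- TRUE
      p <- pH[e]
      if (p == 0L) break
      seen[p] <- TRUE
      e <- cofeExt(p)
      if (e == s) break
    }
  }
  circles == st$r
}

.linearizeCircular <- function(st, pH) {
  D <- .dcjDistancePartners(st$pObs, pH)
  repeat {
    comps <- .familyComponents(st, pH)
    circ <- which(vapply(comps, `[[`, logical(1), "circular"))
    if (!length(circ)) return(pH)
    X <- comps[[circ[1]]]
    linear <- comps[vapply(comps, function(cp) !cp$circular, logical(1))]
    # circle-into-circle merges are sound only between separated covers
    # (occurrence-wise rejoining of wound covers would thread the copies
    # into one chromosome); allow them when both sides are separated
    if (.isSeparatedCover(st, pH, X) && length(circ) > 1L)
      for (ci in circ[-1]) {
        Y <- comps[[ci]]
        if (.isSeparatedCover(st, pH, Y))
          linear <- c(linear, list(Y))
      }
    mergeCandidates <- function(stopAtD) {
      bestD <- NA_integer_; bestCand <- NULL
      for (ai in seq_len(nrow(X$adjs))) {
        circAdj <- .adjOccurrences(st, pH, X$adjs[ai, 2], X$adjs[ai, 1])
        for (tu in linear) for (bi in seq_len(nrow(tu$adjs))) {
          tgtAdj <- .adjOccurrences(st, pH, tu$adjs[bi, 2], tu$adjs[bi, 1])
          for (type in 0:1) {
            cand <- .applyGroupDcj(pH, circAdj, tgtAdj, type)
            D2 <- .dcjDistancePartners(st$pObs, cand)
            if (is.na(bestD) || D2 < bestD) { bestD <- D2; bestCand <- cand }
            if (bestD <= stopAtD) return(list(D = bestD, cand = bestCand))
          }
        }
      }
      list(D = bestD, cand = bestCand)
    }
    splitCandidates <- function(stopAtD) {
      bestD <- NA_integer_; bestCand <- NULL
      for (ai in seq_len(nrow(X$adjs))) {
        circAdj <- .adjOccurrences(st, pH, X$adjs[ai, 2], X$adjs[ai, 1])
        cand <- pH
        for (occ in circAdj) { cand[occ[1]] <- 0L; cand[occ[2]] <- 0L }
        D2 <- .dcjDistancePartners(st$pObs, cand)
        if (is.na(bestD) || D2 < bestD) { bestD <- D2; bestCand <- cand }
        if (bestD <= stopAtD) return(list(D = bestD, cand = bestCand))
      }
      list(D = bestD, cand = bestCand)
    }
    # (a) merge into a linear chromosome group without increasing the
    # distance; (b) otherwise split at no extra cost; (c) otherwise apply
    # the least-increase candidate over both kinds
    m <- mergeCandidates(D)
    if (!is.na(m$D) && m$D <= D) { pH <- m$cand; D <- m$D; next }
    s <- splitCandidates(D)
    if (!is.na(s$D) && s$D <= D) { pH <- s$cand; D <- s$D; next }
    best <- if (!is.na(m$D) && (is.na(s$D) || m$D <= s$D)) m else s
    pH <- best$cand; D <- best$D
  }
}

# Final local minimisation: hill-climb over family-level DCJ moves applied
# symmetrically to all r copies (two adjacencies or an adjacency and a
# telomere rejoined, two telomeres fused, or one adjacency cut).  Every
# move keeps the genome an r-fold cover of a single-copy quotient; moves
# that would create a circular chromosome are rejected, so linearity and
# perfect duplication are preserved.  Only strict distance improvements
# are accepted, so the scan terminates.
.quotientAdjList <- function(st, pH) {
  qp <- integer(2L * st$n)
  for (fe in seq_len(2L * st$n)) {
    p <- pH[.extOf(fe, 1L, st)]
    qp[fe] <- if (p == 0L) 0L else .feOf(p, st)
  }
  fa <- which(qp > 0L & qp > seq_along(qp))
  rbind(cbind(seq_along(qp)[fa], qp[fa]),
        cbind(which(qp == 0L), 0L))
}

.circularAfter <- function(st, pH, fes) {
  cofe <- function(fe) fe + if (fe %% 2L == 1L) 1L else -1L
  qpOf <- function(fe) {
    p <- pH[.extOf(fe, 1L, st)]
    if (p == 0L) 0L else .feOf(p, st)
  }
  for (s in unique(fes[fes > 0L])) {
    cur <- s
    repeat {                       # walk one direction; a cycle returns
      nxt <- qpOf(cur)
      if (nxt == 0L) break
      cur <- cofe(nxt)
      if (cur == s) return(TRUE)
    }
  }
  FALSE
}

.localSearchQuotient <- function(st, pH) {
  local_search_quotient_cpp(st$pObs, pH, st$r)
}

# rebuild a Genome (original family/copy labels) from an uncapped partner
# vector over the aliquoting state's content
.partnersToGenome <- function(st, pH, name) {
  nTel <- sum(pH == 0L)
  pFull <- c(pH, integer(nTel))
  capId <- st$capBase
  for (e in which(pH == 0L)) {
    capId <- capId + 1L
    pFull[e] <- capId; pFull[capId] <- e
  }
  wk <- walk_chromosomes(pFull, st$capBase)
  famIds <- sort(unique(st$content$family))
  copyTab <- lapply(famIds, function(f)
    sort(st$content$copy[st$content$family == f]))
  chroms <- lapply(seq_along(wk$genes), function(i) {
    slots <- wk$genes[[i]]
    s <- abs(slots)
    fidx <- (s - 1L) %/% st$r + 1L
    cidx <- (s - 1L) %% st$r + 1L
    list(family = famIds[fidx],
         copy = vapply(seq_along(s), function(j)
           copyTab[[fidx[j]]][cidx[j]], integer(1)),
         sign = ifelse(slots > 0L, 1L, -1L),
         circular = wk$circular[i])
  })
  new("Genome", name = name, chromosomes = chroms)
}
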