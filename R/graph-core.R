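# Partial graph, contracted partial graph, breakpoint graph, DCJ distance.

#' Partial graph of a genome
#'
#' One vertex per extremity, one black edge per adjacency; the initial
#' partial graph is a perfect matching (every extremity has black degree 1,
#' counting caps per instance).
#'
#' @param x a \code{\linkS4class{Genome}}.
#' @return a \code{\linkS4class{PartialGraph}}.
#' @export
partialGraph <- function(x) {
  adj <- adjacencies(x)
  adj$color <- rep("black", nrow(adj))
  new("PartialGraph", edges = adj)
}

#' Contract a partial graph
#'
#' Merges all extremities of one family into a single vertex (plus one cap
#' vertex); parallel edges collapse with multiplicities and per-copy
#' provenance.
#'
#' @param pg a \code{\linkS4class{PartialGraph}}.
#' @return a \code{\linkS4class{ContractedGraph}}.
#' @examples
#' g <- Genome(list(c(1, 2), c(1, 2)))
#' cg <- contractGraph(partialGraph(g))
#' cg@edges
#' @export
contractGraph <- function(pg) {
  e <- pg@edges
  lab <- function(fam, kind)
    ifelse(kind == "cap", "cap",
           paste0(fam, ifelse(kind == "tail", "t", "h")))
  id <- function(fam, kind)
    ifelse(kind == "cap", 0L, 2L * fam - (kind == "tail"))
  id1 <- id(e$family1, e$kind1); id2 <- id(e$family2, e$kind2)
  c1 <- ifelse(is.na(e$copy1), 0L, e$copy1)
  c2 <- ifelse(is.na(e$copy2), 0L, e$copy2)
  swap <- id1 > id2
  t1 <- ifelse(swap, id2, id1); t2 <- ifelse(swap, id1, id2)
  p1 <- ifelse(swap, c2, c1); p2 <- ifelse(swap, c1, c2)
  key <- paste(t1, t2, e$color)
  ord <- order(t1, t2, e$color, p1, p2)
  groups <- split(ord, key[ord])
  groups <- groups[order(vapply(groups, function(ix) t1[ix[1]] * 1e6 +
                                  t2[ix[1]], numeric(1)))]
  edges <- data.frame(end1 = character(0), end2 = character(0),
                      color = character(0), multiplicity = integer(0),
                      stringsAsFactors = FALSE)
  prov <- list()
  for (ix in groups) {
    i1 <- ix[1]
    edges <- rbind(edges, data.frame(
      end1 = .feLabel(t1[i1]), end2 = .feLabel(t2[i1]), color = e$color[i1],
      multiplicity = length(ix), stringsAsFactors = FALSE))
    prov[[length(prov) + 1L]] <- cbind(copy1 = p1[ix], copy2 = p2[ix])
  }
  new("ContractedGraph", edges = edges, provenance = prov)
}

.checkSameContent <- function(g1, g2) {
  c1 <- .contentTable(g1); c2 <- .contentTable(g2)
  if (nrow(c1) != nrow(c2) ||
      !all(c1$family == c2$family) || !all(c1$copy == c2$copy))
    stop("genomes do not share the same labelled gene content")
  c1
}

#' Breakpoint graph of two genomes
#'
#' @param g1,g2 genomes with identical labelled gene content (the
#'   \code{(family, copy)} sets must be equal; orientation and chromosome
#'   numbers may differ).
#' @return a \code{\linkS4class{BreakpointGraph}} carrying the alternating
#'   cycle and odd path counts of the adjacency-graph formulation.
#' @export
breakpointGraph <- function(g1, g2) {
  content <- .checkSameContent(g1, g2)
  key <- .contentKey(content)
  pa <- .genomePartners(g1, key)
  pb <- .genomePartners(g2, key)
  cnt <- dcj_component_counts(pa, pb)
  new("BreakpointGraph", n = nrow(content), cycles = cnt[1], oddPaths = cnt[2])
}

#' Labelled DCJ distance between two genomes
#'
#' The minimum number of double-cut-and-join operations transforming one
#' genome into the other, computed by the adjacency-graph formulation
#' \eqn{d = N - (C + I/2)} where \eqn{C} counts alternating cycles and
#' \eqn{I} odd paths.  Circular chromosomes are accepted.
#'
#' @inheritParams breakpointGraph
#' @return non-negative integer.
#' @examples
#' a <- Genome(list(c(1, 2, 3)))
#' b <- Genome(list(c(1, -2, 3)))
#' dcjDistance(a, b)   # a single inversion
#' @export
dcjDistance <- function(g1, g2) {
  bg <- breakpointGraph(g1, g2)
  as.integer(bg@n - bg@cycles - bg@oddPaths %/% 2L)
}

# distance between two partner vectors over the same content (internal fast
# path used by the heuristic's candidate evaluation)
.dcjDistancePartners <- function(pa, pb) {
  cnt <- dcj_component_counts(pa, pb)
  as.integer(length(pa) %/% 2L - cnt[1] - cnt[2] %/% 2L)
}

#' Relative DCJ distance
#'
#' Normalises a DCJ distance by the total gene count \code{r * n} of the
#' rearranged duplicated genome.
#'
#' @param D DCJ distance.
#' @param r duplicated size.
#' @param n number of gene families.
#' @return \code{D / (r * n)}.
#' @export
relativeDistance <- function(D, r, n) {
  stopifnot(r >= 1, n >= 1)
  D / (r * n)
}
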