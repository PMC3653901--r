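#' @import methods
NULL

#' Genome: signed, copy-labelled multichromosomal gene orders
#'
#' A \code{Genome} holds an ordered set of chromosomes.  Each chromosome is a
#' list with integer vectors \code{family}, \code{copy}, \code{sign}
#' (\code{+1}/\code{-1}) of equal length and a scalar logical
#' \code{circular}.  Only non-cap genes are stored; the cap genes delimiting
#' a linear chromosome are implicit in the representation and are
#' materialised by \code{\link{extremitySequence}} and
#' \code{\link{adjacencies}}.  Within one genome every \code{(family, copy)}
#' pair is unique.
#'
#' @slot name single character, the genome label.
#' @slot chromosomes list of chromosome records as described above.
#'
#' @seealso \code{\link{Genome}}, \code{\link{readGenomes}}
#' @exportClass Genome
setClass("Genome", representation(name = "character", chromosomes = "list"))

.validChromosome <- function(ch) {
  if (!is.list(ch)) return("chromosome is not a list")
  need <- c("family", "copy", "sign", "circular")
  if (!all(need %in% names(ch))) return("chromosome lacks a required field")
  L <- length(ch$family)
  if (length(ch$copy) != L || length(ch$sign) != L)
    return("family/copy/sign lengths differ")
  if (!is.logical(ch$circular) || length(ch$circular) != 1L)
    return("circular flag must be a single logical")
  if (L > 0) {
    if (any(ch$family < 1L)) return("family IDs must be >= 1 (0 is the cap family)")
    if (any(ch$copy < 1L)) return("copy IDs must be >= 1")
    if (!all(ch$sign %in% c(-1L, 1L))) return("signs must be +1 or -1")
  }
  if (ch$circular && L == 0L) return("a circular chromosome cannot be empty")
  TRUE
}

setValidity("Genome", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  for (ch in object@chromosomes) {
    v <- .validChromosome(ch)
    if (!isTRUE(v)) return(v)
  }
  fam <- unlist(lapply(object@chromosomes, `[[`, "family"))
  cop <- unlist(lapply(object@chromosomes, `[[`, "copy"))
  if (length(fam) && anyDuplicated(paste(fam, cop)))
    return("duplicate (family, copy) gene label")
  TRUE
})

#' Construct a Genome
#'
#' @param chromosomes a list of chromosome records (see
#'   \code{\linkS4class{Genome}}), or a list of signed integer vectors which
#'   are interpreted as linear chromosomes of family IDs with copy IDs
#'   assigned 1..k in encounter order per family.
#' @param name genome label.
#' @param circular logical vector recycled over \code{chromosomes} when they
#'   are given as signed integer vectors.
#' @return a \code{\linkS4class{Genome}}.
#' @examples
#' g <- Genome(list(c(1, -2, 3), c(4, 5)), name = "toy")
#' nGenes(g)
#' @export
Genome <- function(chromosomes = list(), name = "genome", circular = FALSE) {
  circular <- rep_len(as.logical(circular), max(1L, length(chromosomes)))
  chroms <- vector("list", length(chromosomes))
  counter <- new.env(parent = emptyenv())
  for (i in seq_along(chromosomes)) {
    ch <- chromosomes[[i]]
    if (is.numeric(ch)) {
      fam <- abs(as.integer(ch))
      cop <- integer(length(fam))
      for (j in seq_along(fam)) {
        key <- as.character(fam[j])
        k <- if (is.null(counter[[key]])) 0L else counter[[key]]
        counter[[key]] <- k + 1L
        cop[j] <- k + 1L
      }
      chroms[[i]] <- list(family = fam, copy = cop,
                          sign = ifelse(ch < 0, -1L, 1L),
                          circular = circular[i])
    } else {
      ch$family <- as.integer(ch$family)
      ch$copy <- as.integer(ch$copy)
      ch$sign <- as.integer(ch$sign)
      if (is.null(ch$circular)) ch$circular <- circular[i]
      chroms[[i]] <- ch
    }
  }
  new("Genome", name = as.character(name), chromosomes = chroms)
}

setMethod("show", "Genome", function(object) {
  nc <- length(object@chromosomes)
  circ <- sum(vapply(object@chromosomes, `[[`, logical(1), "circular"))
  cat(sprintf("Genome \"%s\": %d gene(s), %d chromosome(s) (%d circular)\n",
              object@name, nGenes(object), nc, circ))
  fs <- familySizes(object)
  if (length(fs))
    cat(sprintf("  %d familie(s); family sizes: %s\n", length(fs),
                paste(sort(unique(fs)), collapse = ", ")))
  shown <- min(nc, 5L)
  for (i in seq_len(shown)) {
    ch <- object@chromosomes[[i]]
    lab <- paste0(ifelse(ch$sign < 0, "-", ""), ch$family, ".", ch$copy)
    cat(sprintf("  [%d] %s %s\n", i, paste(lab, collapse = " "),
                if (ch$circular) "@" else "$"))
  }
  if (nc > shown) cat(sprintf("  ... and %d more chromosome(s)\n", nc - shown))
  invisible(NULL)
})

#' Partial graph of a genome
#'
#' The partial graph ("graph B") has one vertex per extremity of the genome
#' (heads, tails, per-instance caps) and one black edge per adjacency.
#' Inferred edges added during aliquoting are gray.
#'
#' @slot edges data.frame with columns \code{family1, kind1, copy1, family2,
#'   kind2, copy2, color}.
#' @exportClass PartialGraph
setClass("PartialGraph", representation(edges = "data.frame"))

setMethod("show", "PartialGraph", function(object) {
  e <- object@edges
  cat(sprintf("PartialGraph: %d edge(s) (%d black, %d gray)\n",
              nrow(e), sum(e$color == "black"), sum(e$color == "gray")))
  invisible(NULL)
})

#' Contracted partial graph
#'
#' The contracted partial graph ("graph A") merges all extremities of one
#' extremity family into a single vertex; parallel edges collapse into one
#' edge carrying a multiplicity and a provenance list of copy-ID pairs, one
#' per collapsed partial-graph edge.  An edge with multiplicity > 1 is
#' strong, otherwise weak.
#'
#' @slot edges data.frame with columns \code{end1}, \code{end2} (extremity
#'   family labels such as \code{"3t"}, \code{"3h"} or \code{"cap"}),
#'   \code{color} and \code{multiplicity}.
#' @slot provenance list, parallel to the rows of \code{edges}; each element
#'   a two-column integer matrix of copy-ID pairs.
#' @exportClass ContractedGraph
setClass("ContractedGraph",
         representation(edges = "data.frame", provenance = "list"))

setValidity("ContractedGraph", function(object) {
  if (nrow(object@edges) != length(object@provenance))
    return("provenance list length differs from edge count")
  m <- vapply(object@provenance, nrow, integer(1))
  if (any(m != object@edges$multiplicity))
    return("provenance list length must equal multiplicity for every edge")
  if (any(object@edges$multiplicity < 1L))
    return("edges of multiplicity 0 must be absent")
  TRUE
})

setMethod("show", "ContractedGraph", function(object) {
  e <- object@edges
  cat(sprintf("ContractedGraph: %d edge(s), %d strong / %d weak\n",
              nrow(e), sum(e$multiplicity > 1L), sum(e$multiplicity == 1L)))
  invisible(NULL)
})

#' Breakpoint graph summary of two genomes
#'
#' Union of the partial graphs of two genomes with identical labelled gene
#' content, one edge colour per genome.  Only the derived quantities needed
#' for the DCJ distance are stored: the number of alternating cycles and of
#' odd paths (odd number of edges) in the adjacency-graph formulation.
#'
#' @slot n number of shared non-cap genes.
#' @slot cycles alternating cycle count.
#' @slot oddPaths odd path count.
#' @exportClass BreakpointGraph
setClass("BreakpointGraph",
         representation(n = "integer", cycles = "integer", oddPaths = "integer"))

setMethod("show", "BreakpointGraph", function(object) {
  cat(sprintf("BreakpointGraph: n = %d, cycles = %d, odd paths = %d, DCJ distance = %d\n",
              object@n, object@cycles, object@oddPaths,
              object@n - object@cycles - object@oddPaths %/% 2L))
  invisible(NULL)
})

#' Path set returned by the disjoint-path engine
#'
#' @slot u,v endpoint extremity-family labels.
#' @slot paths list; each element a data.frame with columns \code{from},
#'   \code{to}, \code{color} describing one edge path in the contracted
#'   graph.
#' @slot lengths integer vector of path lengths (edge counts).
#' @exportClass PathSet
setClass("PathSet",
         representation(u = "character", v = "character",
                        paths = "list", lengths = "integer"))

setMethod("show", "PathSet", function(object) {
  cat(sprintf("PathSet %s -- %s: %d path(s)%s\n", object@u, object@v,
              length(object@paths),
              if (length(object@lengths))
                sprintf(", lengths {%s}", paste(object@lengths, collapse = ", "))
              else ""))
  invisible(NULL)
})

#' Per-pair score used by weak-adjacency inference
#'
#' @slot np path count.
#' @slot cp alternating-cycles-per-edge-cost ratio.
#' @slot wp combined weight \code{alpha * np + (1 - alpha) * cp}.
#' @slot alpha mixing weight.
#' @slot lengths path lengths underlying \code{cp}.
#' @exportClass PairScore
setClass("PairScore",
         representation(np = "integer", cp = "numeric", wp = "numeric",
                        alpha = "numeric", lengths = "integer"))

setMethod("show", "PairScore", function(object) {
  cat(sprintf("PairScore: N_p = %d, C_p = %.4f, W_p = %.4f (alpha = %g)\n",
              object@np, object@cp, object@wp, object@alpha))
  invisible(NULL)
})

#' Result of the aliquoting heuristic
#'
#' @slot gdup reconstructed perfectly duplicated genome (all-linear).
#' @slot ganc its single-copy quotient.
#' @slot distance inferred DCJ distance between the input and \code{gdup}.
#' @slot relativeDistance \code{distance / (r * n)}.
#' @slot r duplicated size.
#' @slot alpha,depth parameters used.
#' @exportClass AliquotResult
setClass("AliquotResult",
         representation(gdup = "Genome", ganc = "Genome",
                        distance = "numeric", relativeDistance = "numeric",
                        r = "integer", alpha = "numeric", depth = "integer"))

setMethod("show", "AliquotResult", function(object) {
  cat(sprintf("AliquotResult (r = %d, alpha = %g, depth = %d)\n",
              object@r, object@alpha, object@depth))
  cat(sprintf("  inferred DCJ distance: %d (relative %.4f)\n",
              as.integer(object@distance), object@relativeDistance))
  cat(sprintf("  G_dup: %d chromosome(s); G_anc: %d chromosome(s)\n",
              length(object@gdup@chromosomes), length(object@ganc@chromosomes)))
  invisible(NULL)
})
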