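# find_path and pair scoring over the contracted partial graph.

# Internal edge-table form of graph A: list with integer vectors e1, e2
# (family-extremity ids, e1 <= e2), color (0 black / 1 gray), mult, and a
# provenance list of two-column copy matrices aligned with (e1, e2).

.findPathsRaw <- function(A, matchedIds, u, v, maxPaths) {
  verts <- sort(unique(c(A$e1, A$e2, u, v, matchedIds)))
  iu <- match(u, verts) - 1L
  iv <- match(v, verts) - 1L
  ne <- length(A$e1)
  edges <- cbind(match(A$e1, verts) - 1L, match(A$e2, verts) - 1L,
                 A$color, A$mult)
  if (ne == 0L) edges <- matrix(integer(0), 0L, 4L)
  tags <- find_path_tags(edges, verts %in% matchedIds, iu, iv,
                         as.integer(maxPaths))
  lapply(tags, function(tg) {
    list(eidx = abs(tg), dir = sign(tg), len = length(tg))
  })
}

# vertex sequence of one raw path (u, ..., v)
.pathVertices <- function(A, path, u) {
  vs <- u
  cur <- u
  for (i in seq_along(path$eidx)) {
    k <- path$eidx[i]
    a <- if (path$dir[i] > 0L) A$e1[k] else A$e2[k]
    b <- if (path$dir[i] > 0L) A$e2[k] else A$e1[k]
    if (a != cur) stop("discontinuous path")
    cur <- b
    vs <- c(vs, cur)
  }
  vs
}

.validatePathsRaw <- function(A, matchedIds, u, v, paths) {
  usage <- integer(length(A$e1))
  interior <- integer(0)
  for (p in paths) {
    if (p$len < 1L) return("empty path")
    cols <- A$color[p$eidx]
    if (cols[1] != 0L || cols[p$len] != 0L)
      return("path does not start and end with black edges")
    vs <- tryCatch(.pathVertices(A, p, u), error = function(e) NULL)
    if (is.null(vs)) return("discontinuous path")
    if (vs[1] != u || vs[length(vs)] != v) return("path endpoints wrong")
    mid <- vs[-c(1L, length(vs))]
    if (any(mid %in% c(u, v))) return("endpoint used as interior vertex")
    # colour alternation at matched interior vertices
    for (i in seq_along(mid))
      if (mid[i] %in% matchedIds && cols[i] == cols[i + 1L])
        return("no colour alternation at a matched vertex")
    interior <- c(interior, mid[!(mid %in% matchedIds)])
    usage[p$eidx] <- usage[p$eidx] + 1L
  }
  if (any(usage > A$mult))
    return("edge used more often than its multiplicity")
  if (anyDuplicated(interior))
    return("unmatched vertex interior to more than one path position")
  TRUE
}

.graphToRaw <- function(graph) {
  e <- graph@edges
  list(e1 = .feId(e$end1), e2 = .feId(e$end2),
       color = ifelse(e$color == "gray", 1L, 0L),
       mult = as.integer(e$multiplicity),
       prov = graph@provenance)
}

#' Disjoint path search between two extremity-family vertices
#'
#' Finds an edge-path set from \code{u} to \code{v} in a contracted partial
#' graph with (a) the maximum number of paths up to \code{maxPaths} and (b)
#' minimum total length among such sets, subject to: every path starts and
#' ends with black edges; paths alternate edge colours at matched interior
#' vertices; no edge is used more often than its multiplicity; every
#' unmatched vertex is interior to at most one path, at most once.
#'
#' @param graph a \code{\linkS4class{ContractedGraph}}.
#' @param u,v extremity-family labels (e.g. \code{"3t"}, \code{"1h"},
#'   \code{"cap"}); must differ and be present in the graph.
#' @param maxPaths cap on the number of paths (the aliquoting steps use the
#'   duplicated size r).
#' @param matched character vector of matched vertex labels.
#' @return a \code{\linkS4class{PathSet}} (empty when no valid path exists).
#' @export
findPathSet <- function(graph, u, v, maxPaths = 2L, matched = character()) {
  A <- .graphToRaw(graph)
  uid <- .feId(u); vid <- .feId(v)
  present <- unique(c(A$e1, A$e2))
  if (!(uid %in% present) || !(vid %in% present))
    stop("vertex absent from graph")
  raw <- .findPathsRaw(A, .feId(matched), uid, vid, maxPaths)
  paths <- lapply(raw, function(p) {
    vs <- .pathVertices(A, p, uid)
    data.frame(from = .feLabel(vs[-length(vs)]), to = .feLabel(vs[-1L]),
               color = ifelse(A$color[p$eidx] == 1L, "gray", "black"),
               stringsAsFactors = FALSE)
  })
  new("PathSet", u = .feLabel(uid), v = .feLabel(vid), paths = paths,
      lengths = vapply(raw, function(p) p$len, integer(1)))
}

#' Validate a path set against the four path conditions
#'
#' @param graph the \code{\linkS4class{ContractedGraph}} the paths live in.
#' @param pathSet a \code{\linkS4class{PathSet}}.
#' @param matched matched vertex labels.
#' @return TRUE, or a character message describing the violated condition.
#' @export
validatePathSet <- function(graph, pathSet, matched = character()) {
  A <- .graphToRaw(graph)
  uid <- .feId(pathSet@u); vid <- .feId(pathSet@v)
  # rebuild raw paths by matching rows back to edges
  raw <- lapply(pathSet@paths, function(df) {
    eidx <- integer(nrow(df)); dir <- integer(nrow(df))
    for (i in seq_len(nrow(df))) {
      a <- .feId(df$from[i]); b <- .feId(df$to[i])
      col <- ifelse(df$color[i] == "gray", 1L, 0L)
      k <- which(((A$e1 == a & A$e2 == b) | (A$e1 == b & A$e2 == a)) &
                   A$color == col)
      if (!length(k)) return(NULL)
      eidx[i] <- k[1]
      dir[i] <- if (A$e1[k[1]] == a) 1L else -1L
    }
    list(eidx = eidx, dir = dir, len = nrow(df))
  })
  if (any(vapply(raw, is.null, logical(1))))
    return("path contains an edge absent from the graph")
  .validatePathsRaw(A, .feId(matched), uid, vid, raw)
}

.scoreFromStats <- function(np, S, L, alpha) {
  cp <- if (np >= 1L && L > 0L) S / L else 0
  wp <- if (np >= 1L) alpha * np + (1 - alpha) * cp else 0
  list(np = as.integer(np), cp = cp, wp = wp)
}

#' Score a vertex pair for weak-adjacency inference
#'
#' Attaches to a pair (u, v) the path count \eqn{N_p} returned by the path
#' search, the alternating-cycles-per-edge-cost ratio
#' \eqn{C_p = \sum_i \lfloor (L_i+1)/2 \rfloor / \sum_i L_i}, and the
#' combined weight \eqn{W_p = \alpha N_p + (1-\alpha) C_p}.  For a single
#' black cycle of length L this reproduces the three halving cases
#' \eqn{(L+2)/2L}, \eqn{L/2L} and \eqn{(L+1)/2L}.  Pairs with no valid path
#' score 0.
#'
#' @inheritParams findPathSet
#' @param alpha mixing weight between path count and cycle ratio.
#' @return a \code{\linkS4class{PairScore}}.
#' @examples
#' # two identical copies of a circular chromosome give a strong 2-cycle
#' g <- Genome(list(c(1, 2), c(1, 2)), circular = TRUE)
#' cg <- contractGraph(partialGraph(g))
#' scorePair(cg, "1h", "2t", maxPaths = 2)
#' @export
scorePair <- function(graph, u, v, alpha = 0.5, maxPaths = 2L,
                      matched = character()) {
  ps <- findPathSet(graph, u, v, maxPaths = maxPaths, matched = matched)
  L <- sum(ps@lengths)
  S <- sum((ps@lengths + 1L) %/% 2L)
  st <- .scoreFromStats(length(ps@paths), S, L, alpha)
  new("PairScore", np = st$np, cp = st$cp, wp = st$wp, alpha = alpha,
      lengths = ps@lengths)
}
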