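# Simulation of (G_anc, G_dup, G_obs) data points: a random single-copy
# ancestor, an r-way whole-genome duplication, and D_N random DCJ
# operations.

#' Random single-copy ancestor genome
#'
#' Generates the identity-ordered family sequence 1..n and breaks it into m
#' segments at m - 1 uniformly chosen distinct breakpoints, with m uniform
#' on [1, m0]; all genes are on the positive strand.
#'
#' @param n number of gene families.
#' @param m0 maximum number of chromosomes (<= n).
#' @param name genome label.
#' @return a single-copy \code{\linkS4class{Genome}}.
#' @export
randomSingleCopyGenome <- function(n, m0 = 1L, name = "anc") {
  stopifnot(n >= 1, m0 >= 1)
  if (m0 > n) stop("m0 must not exceed the number of families")
  m <- sample.int(m0, 1L)
  breaks <- if (m > 1L) sort(sample.int(n - 1L, m - 1L)) else integer(0)
  bounds <- c(0L, breaks, n)
  chroms <- lapply(seq_len(m), function(i)
    seq.int(bounds[i] + 1L, bounds[i + 1L]))
  Genome(chroms, name = name)
}

#' r-way whole-genome duplication
#'
#' Duplicates a single-copy genome into r copies; genes of the same family
#' receive copy IDs 1..r by copy index.  The result is perfectly
#' duplicated.
#'
#' @param x a single-copy \code{\linkS4class{Genome}}.
#' @param r number of copies (>= 2 for a duplication; 1 returns the input
#'   relabelled).
#' @return a \code{\linkS4class{Genome}} with r chromosome-set copies.
#' @examples
#' wgd(Genome(list(1:2)), 2)
#' @export
wgd <- function(x, r) {
  stopifnot(is(x, "Genome"), r >= 1)
  fs <- familySizes(x)
  if (length(fs) && any(fs != 1L)) stop("input is not a single-copy genome")
  chroms <- list()
  for (cp in seq_len(r))
    for (ch in x@chromosomes) {
      ch$copy <- rep(as.integer(cp), length(ch$copy))
      chroms[[length(chroms) + 1L]] <- ch
    }
  new("Genome", name = paste0(x@name, "_x", r), chromosomes = chroms)
}

#' Apply random DCJ operations
#'
#' Performs k operations; each picks two distinct adjacencies (telomeric
#' included) uniformly and one of the two rejoinings uniformly, rejecting
#' and redrawing candidates that would produce a circular chromosome, so
#' that the output remains all-linear with unchanged gene content.  Uses
#' R's RNG stream (seed with \code{set.seed}).
#'
#' @param x an all-linear \code{\linkS4class{Genome}}.
#' @param k number of operations (>= 0).
#' @return the rearranged \code{\linkS4class{Genome}}.
#' @export
applyRandomDcj <- function(x, k) {
  stopifnot(is(x, "Genome"), k >= 0)
  if (k == 0L) return(x)
  if (any(vapply(x@chromosomes, `[[`, logical(1), "circular")))
    stop("input must be all-linear")
  content <- .contentTable(x)
  key <- .contentKey(content)
  N2 <- 2L * nrow(content)
  p <- .genomePartners(x, key)
  # cap the telomeres
  capId <- N2
  for (ch in x@chromosomes) {
    if (length(ch$family) == 0L) next
    s <- .chromSlots(ch, key)
    e1 <- .entryExt(s[1], ch$sign[1])
    e2 <- .exitExt(s[length(s)], ch$sign[length(ch$sign)])
    p <- c(p, e1, e2)
    p[e1] <- capId + 1L; p[e2] <- capId + 2L
    capId <- capId + 2L
  }
  p2 <- random_dcj_ops(p, N2, as.integer(k))
  wk <- walk_chromosomes(p2, N2)
  chroms <- lapply(seq_along(wk$genes), function(i) {
    slots <- wk$genes[[i]]
    s <- abs(slots)
    list(family = content$family[s], copy = content$copy[s],
         sign = ifelse(slots > 0L, 1L, -1L),
         circular = wk$circular[i])
  })
  new("Genome", name = x@name, chromosomes = chroms)
}

#' Simulate a dataset of aliquoting data points
#'
#' Each data point holds a random single-copy ancestor G_anc (n families, m
#' uniform on [1, m0] chromosomes), its r-way duplication G_dup, and the
#' observed genome G_obs obtained by D_N random DCJ operations, with D_N
#' uniform on [1, r*n] (or fixed).  The per-point RNG stream is derived
#' from the master seed and the point index, so individual points are
#' reproducible.
#'
#' @param count number of data points.
#' @param n gene families per genome.
#' @param m0 maximum ancestor chromosome number.
#' @param r duplicated size.
#' @param dN \code{"uniform"} (default) or a fixed operation count.
#' @param seed master seed (optional; when NULL the current RNG state is
#'   used to draw point seeds).
#' @return a list with \code{records} (per point: \code{ganc}, \code{gdup},
#'   \code{gobs}, \code{dN}, \code{simD}, \code{simRel}) and \code{table}, a
#'   data.frame summary.
#' @export
simulateDataset <- function(count, n = 100L, m0 = 2L, r = 3L,
                            dN = "uniform", seed = NULL) {
  stopifnot(count >= 0, r >= 2)
  if (!is.null(seed)) set.seed(seed)
  pointSeeds <- sample.int(.Machine$integer.max - 1L, count)
  records <- vector("list", count)
  for (i in seq_len(count)) {
    set.seed(pointSeeds[i])
    ganc <- randomSingleCopyGenome(n, m0, name = paste0("anc_", i))
    gdup <- wgd(ganc, r)
    dNi <- if (identical(dN, "uniform")) sample.int(r * n, 1L)
           else as.integer(dN)
    if (dNi < 1L || dNi > r * n)
      stop("dN must lie in [1, r*n]")
    gobs <- applyRandomDcj(gdup, dNi)
    gobs@name <- paste0("obs_", i)
    simD <- dcjDistance(gobs, gdup)
    records[[i]] <- list(ganc = ganc, gdup = gdup, gobs = gobs,
                         dN = dNi, simD = simD,
                         simRel = relativeDistance(simD, r, n))
  }
  tab <- data.frame(
    point = seq_len(count),
    n = rep(as.integer(n), count), m0 = rep(as.integer(m0), count),
    r = rep(as.integer(r), count),
    dN = vapply(records, `[[`, integer(1), "dN"),
    simD = vapply(records, `[[`, integer(1), "simD"),
    simRel = vapply(records, `[[`, numeric(1), "simRel"))
  list(records = records, table = tab)
}
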