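# Genome-level operations: extremities, adjacencies, perfect duplication.
#
# Internal extremity coding.  Extremity families: cap = 0, tail of family f
# = 2f-1, head = 2f.  Labelled extremities of a genome with content table
# (family, copy) sorted by (family, copy): gene slot s has tail 2s-1 and
# head 2s; caps get indices above 2N when a capped representation is needed.

.contentTable <- function(genome) {
  fam <- unlist(lapply(genome@chromosomes, `[[`, "family"))
  cop <- unlist(lapply(genome@chromosomes, `[[`, "copy"))
  if (!length(fam)) return(data.frame(family = integer(0), copy = integer(0)))
  o <- order(fam, cop)
  data.frame(family = as.integer(fam[o]), copy = as.integer(cop[o]))
}

.contentKey <- function(content) paste(content$family, content$copy)

# slot numbers of a chromosome's genes within a content table
.chromSlots <- function(ch, contentKey) {
  match(paste(ch$family, ch$copy), contentKey)
}

# entry/exit extremity indices for a signed gene at slot s:
# +g enters by the tail (2s-1) and exits by the head (2s); -g the reverse.
.entryExt <- function(slot, sign) ifelse(sign > 0L, 2L * slot - 1L, 2L * slot)
.exitExt <- function(slot, sign) ifelse(sign > 0L, 2L * slot, 2L * slot - 1L)

# Partner vector over labelled extremities 1..2N; 0 marks a telomere.
.genomePartners <- function(genome, contentKey) {
  N2 <- 2L * length(contentKey)
  p <- integer(N2)
  for (ch in genome@chromosomes) {
    L <- length(ch$family)
    if (L == 0L) next
    s <- .chromSlots(ch, contentKey)
    if (anyNA(s)) stop("gene content mismatch")
    ent <- .entryExt(s, ch$sign)
    ext <- .exitExt(s, ch$sign)
    if (L > 1L) {
      a <- ext[-L]; b <- ent[-1L]
      p[a] <- b; p[b] <- a
    }
    if (ch$circular) {
      p[ext[L]] <- ent[1L]; p[ent[1L]] <- ext[L]
    }
    # linear ends stay 0 (telomeres)
  }
  p
}

# family-extremity id of a labelled extremity index (content table needed)
.extFamilyId <- function(idx, content) {
  slot <- (idx + 1L) %/% 2L
  fam <- content$family[slot]
  ifelse(idx %% 2L == 1L, 2L * fam - 1L, 2L * fam)
}

.feLabel <- function(id) {
  ifelse(id == 0L, "cap",
         paste0((id + 1L) %/% 2L, ifelse(id %% 2L == 1L, "t", "h")))
}

.feId <- function(label) {
  out <- integer(length(label))
  for (i in seq_along(label)) {
    lb <- label[i]
    if (lb %in% c("cap", "0")) { out[i] <- 0L; next }
    fam <- as.integer(sub("[th]$", "", lb))
    out[i] <- if (grepl("t$", lb)) 2L * fam - 1L else 2L * fam
  }
  out
}

#' Extremity sequence of a chromosome
#'
#' Replaces every non-cap gene \code{+g} by the ordered pair (tail, head)
#' and \code{-g} by (head, tail); a linear chromosome additionally starts
#' and ends with a cap extremity.
#'
#' @param x a \code{\linkS4class{Genome}}.
#' @param chrom chromosome index.
#' @return data.frame with columns \code{family}, \code{kind} (one of
#'   \code{"cap"}, \code{"tail"}, \code{"head"}) and \code{copy} (NA for
#'   caps).
#' @examples
#' g <- Genome(list(c(1, -2)))
#' extremitySequence(g, 1)
#' @export
extremitySequence <- function(x, chrom = 1L) {
  stopifnot(is(x, "Genome"))
  ch <- x@chromosomes[[chrom]]
  L <- length(ch$family)
  fam <- rep(ch$family, each = 2L)
  cop <- rep(ch$copy, each = 2L)
  kind <- character(2L * L)
  if (L) {
    first <- ifelse(ch$sign > 0L, "tail", "head")
    second <- ifelse(ch$sign > 0L, "head", "tail")
    kind[seq(1L, 2L * L, by = 2L)] <- first
    kind[seq(2L, 2L * L, by = 2L)] <- second
  }
  out <- data.frame(family = fam, kind = kind, copy = cop,
                    stringsAsFactors = FALSE)
  if (!ch$circular) {
    cap <- data.frame(family = 0L, kind = "cap", copy = NA_integer_)
    out <- rbind(cap, out, cap)
  }
  out
}

#' Adjacency set of a genome
#'
#' One row per adjacency: the unordered pair of extremities of consecutive
#' genes.  A genome with G non-cap genes and K linear chromosomes has
#' exactly G + K adjacencies; telomeric adjacencies pair an extremity with a
#' cap.
#'
#' @param x a \code{\linkS4class{Genome}}.
#' @return data.frame with columns \code{family1, kind1, copy1, family2,
#'   kind2, copy2}; caps have kind \code{"cap"} and NA copy.
#' @export
adjacencies <- function(x) {
  stopifnot(is(x, "Genome"))
  rows <- list()
  for (i in seq_along(x@chromosomes)) {
    es <- extremitySequence(x, i)
    n <- nrow(es)
    if (n == 0L) next
    ch <- x@chromosomes[[i]]
    if (ch$circular) {
      a <- seq(2L, n, by = 2L)
      b <- c(seq(3L, n, by = 2L), 1L)
    } else {
      a <- seq(1L, n - 1L, by = 2L)
      b <- a + 1L
    }
    rows[[length(rows) + 1L]] <-
      data.frame(family1 = es$family[a], kind1 = es$kind[a], copy1 = es$copy[a],
                 family2 = es$family[b], kind2 = es$kind[b], copy2 = es$copy[b],
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(family1 = integer(0), kind1 = character(0),
                      copy1 = integer(0), family2 = integer(0),
                      kind2 = character(0), copy2 = integer(0)))
  do.call(rbind, rows)
}

# lexicographic minimum of a signed family sequence and its reversed-negated
# form; for circular chromosomes the minimum over all rotations of both.
.canonicalSeq <- function(seq, circular) {
  if (!length(seq)) return("")
  rev_neg <- -rev(seq)
  if (!circular) {
    a <- paste(seq, collapse = " ")
    b <- paste(rev_neg, collapse = " ")
    return(min(a, b))
  }
  best <- NULL
  L <- length(seq)
  for (cand in list(seq, rev_neg)) {
    for (k in seq_len(L)) {
      rot <- cand[c(k:L, seq_len(k - 1L))]
      key <- paste(rot, collapse = " ")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

.chromCanonicalKeys <- function(genome) {
  vapply(genome@chromosomes, function(ch) {
    paste0(if (ch$circular) "@" else "$", " ",
           .canonicalSeq(ch$sign * ch$family, ch$circular))
  }, character(1))
}

#' Test for perfect duplication
#'
#' A genome is perfectly duplicated with duplicated size \code{r} when every
#' non-cap family has size exactly \code{r} and the family-level multiset of
#' orientation-canonicalised chromosomes has every count divisible by
#' \code{r} -- i.e. the genome consists of r interchangeable copies of a
#' single-copy genome.
#'
#' @param x a \code{\linkS4class{Genome}}.
#' @param r duplicated size, >= 2.
#' @return logical.
#' @seealso \code{\link{quotientGenome}} for the single-copy representative.
#' @export
isPerfectlyDuplicated <- function(x, r) {
  stopifnot(is(x, "Genome"), r >= 2)
  fs <- familySizes(x)
  if (!length(fs)) return(TRUE)
  if (!all(fs == r)) return(FALSE)
  keys <- .chromCanonicalKeys(x)
  keys <- keys[vapply(x@chromosomes, function(ch) length(ch$family) > 0L,
                      logical(1))]
  all(table(keys) %% r == 0L)
}

#' Single-copy quotient of a perfectly duplicated genome
#'
#' Keeps one representative chromosome per group of \code{r} identical
#' (family-level, orientation-canonicalised) chromosomes, relabelling all
#' copy IDs to 1.
#'
#' @inheritParams isPerfectlyDuplicated
#' @return a \code{\linkS4class{Genome}} named \code{<name>_anc}.
#' @export
quotientGenome <- function(x, r) {
  if (!isPerfectlyDuplicated(x, r))
    stop("genome is not perfectly duplicated with r = ", r)
  keys <- .chromCanonicalKeys(x)
  nonEmpty <- which(vapply(x@chromosomes, function(ch)
    length(ch$family) > 0L, logical(1)))
  seen <- new.env(parent = emptyenv())
  keep <- list()
  for (i in nonEmpty) {
    k <- keys[i]
    cnt <- if (is.null(seen[[k]])) 0L else seen[[k]]
    seen[[k]] <- cnt + 1L
    if (cnt %% r == 0L) {   # first of each group of r
      ch <- x@chromosomes[[i]]
      ch$copy <- rep(1L, length(ch$copy))
      keep[[length(keep) + 1L]] <- ch
    }
  }
  new("Genome", name = paste0(x@name, "_anc"), chromosomes = keep)
}
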