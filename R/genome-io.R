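# GRIMM-like genome file I/O.
#
# Dialect: lines ">name" start a genome; each following non-empty line is
# one chromosome of whitespace-separated signed family IDs with an optional
# ".copy" suffix (e.g. "-3.2"), terminated by "$" (linear) or "@"
# (circular).  "#" starts a comment.  Cap genes are never written; "$"
# already marks linear ends.  Copy IDs omitted in a file are assigned 1..k
# per family in left-to-right encounter order.

.parseToken <- function(tok) {
  m <- regmatches(tok, regexec("^([+-]?)([0-9]+)(\\.([0-9]+))?$", tok))[[1]]
  if (!length(m)) stop("malformed gene token: '", tok, "'")
  fam <- as.integer(m[3])
  if (fam == 0L) stop("family ID 0 is reserved for cap genes: '", tok, "'")
  copy <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  c(fam = fam, copy = copy, sign = if (m[2] == "-") -1L else 1L)
}

#' Read genomes from a GRIMM-like file
#'
#' @param file path or connection; alternatively pass the file content
#'   through \code{text}.
#' @param text optional character vector of lines, used instead of
#'   \code{file}.
#' @return a list of \code{\linkS4class{Genome}} objects (one per ">name"
#'   header).
#' @examples
#' gs <- readGenomes(text = c(">toy", "1 -2 $", "3 @"))
#' gs[[1]]
#' @export
readGenomes <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  genomes <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) genomes[[length(genomes) + 1L]] <<- .finishGenome(cur)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur <- list(name = trimws(substring(ln, 2L)), chroms = list())
    } else {
      if (is.null(cur)) stop("chromosome line before any '>' header")
      cur$chroms[[length(cur$chroms) + 1L]] <- ln
    }
  }
  flush()
  genomes
}

.finishGenome <- function(cur) {
  chroms <- list()
  assigned <- new.env(parent = emptyenv())  # family -> used copy IDs
  for (ln in cur$chroms) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    term <- toks[length(toks)]
    if (!term %in% c("$", "@"))
      stop("chromosome line lacks a '$' or '@' terminator: '", ln, "'")
    toks <- toks[-length(toks)]
    if (any(toks %in% c("$", "@")))
      stop("mixed topology markers in one chromosome line: '", ln, "'")
    parsed <- lapply(toks, .parseToken)
    fam <- vapply(parsed, `[[`, integer(1), "fam")
    cop <- vapply(parsed, `[[`, integer(1), "copy")
    sgn <- vapply(parsed, `[[`, integer(1), "sign")
    chroms[[length(chroms) + 1L]] <-
      list(family = fam, copy = cop, sign = sgn, circular = term == "@")
  }
  # explicit copy IDs first, then fill omitted ones with the smallest unused
  for (ch in chroms)
    for (j in seq_along(ch$family))
      if (!is.na(ch$copy[j])) {
        key <- as.character(ch$family[j])
        assigned[[key]] <- c(assigned[[key]], ch$copy[j])
      }
  for (i in seq_along(chroms)) {
    ch <- chroms[[i]]
    for (j in seq_along(ch$family))
      if (is.na(ch$copy[j])) {
        key <- as.character(ch$family[j])
        used <- assigned[[key]]
        cand <- 1L
        while (cand %in% used) cand <- cand + 1L
        assigned[[key]] <- c(used, cand)
        ch$copy[j] <- cand
      }
    chroms[[i]] <- ch
  }
  g <- new("Genome", name = cur$name, chromosomes = chroms)
  validObject(g)
  g
}

#' Write genomes in the GRIMM-like dialect
#'
#' Copy IDs are always written explicitly so that
#' \code{readGenomes(text = writeGenomes(g))} round-trips.
#'
#' @param x a \code{\linkS4class{Genome}} or a list of them.
#' @param file optional path; when NULL the lines are returned invisibly.
#' @return character vector of lines, invisibly when written to a file.
#' @export
writeGenomes <- function(x, file = NULL) {
  if (is(x, "Genome")) x <- list(x)
  lines <- character(0)
  for (g in x) {
    lines <- c(lines, paste0(">", g@name))
    for (ch in g@chromosomes) {
      lab <- paste0(ifelse(ch$sign < 0L, "-", ""), ch$family, ".", ch$copy)
      lines <- c(lines, paste(c(lab, if (ch$circular) "@" else "$"),
                              collapse = " "))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
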