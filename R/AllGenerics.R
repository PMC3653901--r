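#' @rdname Genome
#' @param x,object a \code{\linkS4class{Genome}}.
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname Genome
#' @export
setGeneric("genomeName", function(x) standardGeneric("genomeName"))

#' @rdname Genome
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname Genome
#' @export
setGeneric("familySizes", function(x) standardGeneric("familySizes"))

#' @rdname Genome
#' @export
setGeneric("duplicatedSize", function(x) standardGeneric("duplicatedSize"))

setMethod("chromosomes", "Genome", function(x) x@chromosomes)
setMethod("genomeName", "Genome", function(x) x@name)
setMethod("nGenes", "Genome", function(x)
  sum(vapply(x@chromosomes, function(ch) length(ch$family), integer(1))))
setMethod("familySizes", "Genome", function(x) {
  fam <- unlist(lapply(x@chromosomes, `[[`, "family"))
  if (!length(fam)) return(integer(0))
  tab <- table(fam)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
})
setMethod("duplicatedSize", "Genome", function(x) {
  fs <- familySizes(x)
  if (!length(fs)) return(NA_integer_)
  u <- unique(fs)
  if (length(u) == 1L) u else NA_integer_
})
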