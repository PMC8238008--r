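#' Extract the feature GRanges from a GenomeAnnotation
#' @param x a `GenomeAnnotation`.
#' @return a `GRanges`.
#' @export
setGeneric("annFeatures", function(x) standardGeneric("annFeatures"))

#' Gene-level GRanges of an annotation
#' @param x a `GenomeAnnotation`.
#' @return `GRanges` of features with `type == "gene"`.
#' @export
setGeneric("annGenes", function(x) standardGeneric("annGenes"))

#' Transcript-level GRanges of an annotation
#' @param x a `GenomeAnnotation`.
#' @return `GRanges` of features with `type == "mRNA"`.
#' @export
setGeneric("annTranscripts", function(x) standardGeneric("annTranscripts"))

#' Catalog table accessor
#' @param x a `KinaseCatalog`.
#' @return the underlying data.frame.
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))

#' Catalog status accessor
#' @param x a `KinaseCatalog`.
#' @return named character vector protein_id -> status.
#' @export
setGeneric("catalogStatus", function(x) standardGeneric("catalogStatus"))

#' Catalog family accessor
#' @param x a `KinaseCatalog`.
#' @return named character vector protein_id -> family (NA when unassigned).
#' @export
setGeneric("catalogFamilies", function(x) standardGeneric("catalogFamilies"))

#' Apply a concordance decision to a catalog
#' @param x a `KinaseCatalog`.
#' @param status named character vector protein_id -> {bona_fide, UNK}.
#' @return the updated `KinaseCatalog`.
#' @export
setGeneric("setCatalogStatus", function(x, status) standardGeneric("setCatalogStatus"))

#' @describeIn annFeatures method for GenomeAnnotation
#' @export
setMethod("annFeatures", "GenomeAnnotation", function(x) x@features)

#' @describeIn annGenes method for GenomeAnnotation
#' @export
setMethod("annGenes", "GenomeAnnotation", function(x) {
  gr <- x@features
  gr[S4Vectors::mcols(gr)$type == "gene"]
})

#' @describeIn annTranscripts method for GenomeAnnotation
#' @export
setMethod("annTranscripts", "GenomeAnnotation", function(x) {
  gr <- x@features
  gr[S4Vectors::mcols(gr)$type == "mRNA"]
})

#' @describeIn catalogTable method for KinaseCatalog
#' @export
setMethod("catalogTable", "KinaseCatalog", function(x) x@table)

#' @describeIn catalogStatus method for KinaseCatalog
#' @export
setMethod("catalogStatus", "KinaseCatalog", function(x)
  stats::setNames(x@table$status, x@table$protein_id))

#' @describeIn catalogFamilies method for KinaseCatalog
#' @export
setMethod("catalogFamilies", "KinaseCatalog", function(x)
  stats::setNames(x@table$family, x@table$protein_id))

#' @describeIn setCatalogStatus method for KinaseCatalog
#' @export
setMethod("setCatalogStatus", "KinaseCatalog", function(x, status) {
  stopifnot(all(names(status) %in% x@table$protein_id))
  idx <- match(names(status), x@table$protein_id)
  x@table$status[idx] <- unname(status)
  validObject(x)
  x
})

#' @export
setMethod("show", "GenomeAnnotation", function(object) {
  gr <- object@features
  tt <- table(as.character(S4Vectors::mcols(gr)$type))
  cat("GenomeAnnotation:", sum(tt[names(tt) == "gene"]), "genes on",
      length(GenomeInfoDb::seqlevels(gr)), "sequences\n")
  cat("  features:", paste(sprintf("%s=%d", names(tt), as.integer(tt)),
                           collapse = ", "), "\n")
})

#' @export
setMethod("show", "KinaseCatalog", function(object) {
  tb <- object@table
  cat("KinaseCatalog with", nrow(tb), "loci;",
      length(unique(stats::na.omit(tb$family))), "families\n")
  cat("  status:", paste(sprintf("%s=%d", names(table(tb$status)),
                                 as.integer(table(tb$status))), collapse = ", "), "\n")
})

#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_genes, "genes on", object@n_chromosomes,
      "chromosomes of", object@chrom_length, "bp; seed", object@seed, "\n")
  cat("  kinase families:", length(object@family_sizes),
      "| planted duplication pairs:", sum(object@duplication_plan$count), "\n")
})
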