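#' Build a GenomeAnnotation from a feature table
#'
#' @param features data.frame with columns `seqid`, `start`, `end`, `strand`,
#'   `type`, `ID`, `Parent` (1-based inclusive coordinates).
#' @param seqlengths optional named vector of chromosome lengths.
#' @return a [GenomeAnnotation-class].
#' @export
makeGenomeAnnotation <- function(features, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- as.character(features$type)
  S4Vectors::mcols(gr)$ID <- as.character(features$ID)
  S4Vectors::mcols(gr)$Parent <- as.character(features$Parent)
  if (!is.null(seqlengths)) GenomeInfoDb::seqlengths(gr) <- seqlengths
  new("GenomeAnnotation", features = gr)
}

#' Read a GFF3 file into a GenomeAnnotation
#'
#' @param path GFF3 file (1-based inclusive coordinates, version 3).
#' @return a [GenomeAnnotation-class].
#' @export
readGenomeAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- md$Parent
  if (!is.null(parent) && !is.character(parent)) {
    parent <- vapply(as.list(parent), function(p)
      if (length(p)) paste(p, collapse = ",") else NA_character_, character(1))
  }
  keep <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                 IRanges::IRanges(BiocGenerics::start(gr),
                                                  BiocGenerics::end(gr)),
                                 strand = BiocGenerics::strand(gr))
  S4Vectors::mcols(keep)$type <- as.character(md$type)
  S4Vectors::mcols(keep)$ID <- as.character(md$ID)
  S4Vectors::mcols(keep)$Parent <- parent
  GenomeInfoDb::seqinfo(keep) <- GenomeInfoDb::seqinfo(gr)
  # honor ##sequence-region pragmas (not all readers surface them)
  pragmas <- grep("^##sequence-region", readLines(path, n = 200), value = TRUE)
  if (length(pragmas)) {
    parts <- strsplit(trimws(pragmas), "\\s+")
    nm <- vapply(parts, `[`, "", 2)
    len <- as.integer(vapply(parts, `[`, "", 4))
    keepn <- nm %in% GenomeInfoDb::seqlevels(keep)
    if (any(keepn)) {
      sl <- GenomeInfoDb::seqlengths(keep)
      sl[nm[keepn]] <- len[keepn]
      GenomeInfoDb::seqlengths(keep) <- sl
    }
  }
  new("GenomeAnnotation", features = keep)
}

#' Write a GenomeAnnotation as GFF3
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGenomeAnnotation <- function(annotation, path) {
  gr <- annFeatures(annotation)
  md <- S4Vectors::mcols(gr)
  out <- gr
  parent <- md$Parent
  pl <- ifelse(is.na(parent), "", parent)
  # CDS phase: offset to the next codon start, accumulated in transcription
  # order within each transcript
  phase <- rep(NA_integer_, length(gr))
  is_cds <- md$type == "CDS"
  for (tx in unique(md$Parent[is_cds])) {
    idx <- which(is_cds & md$Parent == tx)
    minus <- as.character(BiocGenerics::strand(gr[idx[1]])) == "-"
    idx <- idx[order(BiocGenerics::start(gr[idx]), decreasing = minus)]
    w <- BiocGenerics::width(gr[idx])
    before <- c(0L, cumsum(w)[-length(w)])
    phase[idx] <- (3L - before %% 3L) %% 3L
  }
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    type = md$type, ID = md$ID,
    Parent = IRanges::CharacterList(ifelse(nzchar(pl),
                                           strsplit(pl, ","), list(character(0)))),
    phase = phase)
  rtracklayer::export(out, path, format = "gff3")
  # drop volatile header comments (date/tool version) so fixed-seed outputs
  # are byte-identical across runs and days; declare sequence lengths
  lines <- readLines(path)
  lines <- lines[!grepl("^##(date|source-version|sequence-region)", lines)]
  sl <- GenomeInfoDb::seqlengths(gr)
  pragma <- sprintf("##sequence-region %s 1 %d",
                    names(sl)[!is.na(sl)], sl[!is.na(sl)])
  writeLines(append(lines, pragma, after = 1L), path)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits the genome, proteins and CDS as FASTA, the annotation as GFF3, the
#' hit and similarity tables as TSV, the planted motifs in JASPAR PFM format,
#' the evolved CDS pairs as FASTA, and every truth table as TSV, all under one
#' directory. Outputs are plain text and byte-identical for a fixed config
#' seed.
#'
#' @param sim result of [genGenome()].
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  paths <- c(
    genome = p("genome.fa"), proteins = p("proteins.fa"), cds = p("cds.fa"),
    gff = p("annotation.gff3"), domain_hits = p("domain_hits.tsv"),
    similarity = p("similarity.tsv"), pwms = p("motifs.pfm"),
    kaks = p("kaks_pairs.fa"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  Biostrings::writeXStringSet(sim$proteins, paths["proteins"])
  Biostrings::writeXStringSet(sim$cds, paths["cds"])
  writeGenomeAnnotation(sim$annotation, paths["gff"])
  wtsv <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(sim$domain_hits, paths["domain_hits"])
  wtsv(sim$similarity, paths["similarity"])
  writeJasparPfm(sim$pwms, paths["pwms"])
  kk <- Biostrings::DNAStringSet(unlist(lapply(sim$kaks_pairs, function(x)
    stats::setNames(c(x$cds1, x$cds2),
                    paste0(x$pair_id, c(".anc", ".der"))))))
  Biostrings::writeXStringSet(kk, paths["kaks"])
  for (nm in names(sim$truth)) {
    f <- p(sprintf("truth_%s.tsv", nm))
    wtsv(sim$truth[[nm]], f)
    paths[paste0("truth_", nm)] <- f
  }
  invisible(paths)
}

#' Write a kinase catalog as TSV
#'
#' @param catalog a [KinaseCatalog-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  utils::write.table(catalogTable(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tree in Newick format with support values as internal-node labels
#'
#' @param tree a `phylo` (optionally with `node.label` support values).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
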