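#' Default Pfam kinase-domain models
#'
#' Protein kinase domain (PF00069), protein tyrosine kinase (PF07714) and
#' ABC1 atypical kinase (PF00481): a protein is a kinase candidate when it
#' carries a qualifying hit to any of these models.
#' @export
KINASE_MODELS <- c("PF00069", "PF07714", "PF00481")

.checkHits <- function(hits) {
  need <- c("protein_id", "model_id", "model_from", "model_to",
            "model_length", "evalue", "bit_score")
  missing_cols <- setdiff(need, colnames(hits))
  if (length(missing_cols))
    stop("hit table missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(is.na(hits$model_length)) || any(hits$model_length < 1))
    stop("hit with unknown or invalid model_length")
  bad <- hits$model_from < 1 | hits$model_from > hits$model_to |
    hits$model_to > hits$model_length
  if (any(bad))
    stop("malformed model coordinates for protein ",
         paste(unique(hits$protein_id[bad]), collapse = ", "))
  if (any(hits$evalue < 0)) stop("negative e-value")
  invisible(hits)
}

#' Identify kinase candidates from domain hits
#'
#' A protein is a candidate if it has at least one hit covering at least
#' `min_model_coverage` of a kinase-domain model; its number of kinase domains
#' is the number of qualifying hits.
#'
#' @param hits data.frame of domain hits (columns `protein_id`, `model_id`,
#'   `model_from`, `model_to`, `model_length`, `evalue`, `bit_score`).
#' @param min_model_coverage minimum fraction of the model covered
#'   (`(model_to - model_from + 1) / model_length`), default 0.5.
#' @param kinase_models model ids accepted as kinase domains.
#' @return data.frame `protein_id`, `n_kinase_domains` (one row per
#'   candidate).
#' @export
identifyKinases <- function(hits, min_model_coverage = 0.5,
                            kinase_models = KINASE_MODELS) {
  .checkHits(hits)
  kin <- hits[hits$model_id %in% kinase_models, , drop = FALSE]
  cov <- (kin$model_to - kin$model_from + 1) / kin$model_length
  kin <- kin[cov >= min_model_coverage, , drop = FALSE]
  if (!nrow(kin))
    return(data.frame(protein_id = character(0),
                      n_kinase_domains = integer(0)))
  tt <- table(kin$protein_id)
  out <- data.frame(protein_id = names(tt),
                    n_kinase_domains = as.integer(tt),
                    stringsAsFactors = FALSE)
  out[order(out$protein_id), , drop = FALSE]
}

#' Assign kinase families from family-HMM hits
#'
#' The family is the model of the best hit with `evalue < evalue_cutoff`;
#' proteins with no passing hit stay unassigned (`NA`). Ties are broken by
#' lower e-value, then higher bit score, then lexicographic model id.
#'
#' @param family_hits data.frame of hits against family HMMs (same columns as
#'   [identifyKinases()]).
#' @param evalue_cutoff e-value threshold (strict `<`), default `1e-5`.
#' @return named character vector protein_id -> family (NA if unassigned).
#' @export
assignFamilies <- function(family_hits, evalue_cutoff = 1e-5) {
  .checkHits(family_hits)
  fam <- stats::setNames(rep(NA_character_,
                             length(unique(family_hits$protein_id))),
                         sort(unique(family_hits$protein_id)))
  pass <- family_hits[family_hits$evalue < evalue_cutoff, , drop = FALSE]
  if (nrow(pass)) {
    ord <- order(pass$protein_id, pass$evalue, -pass$bit_score, pass$model_id)
    pass <- pass[ord, , drop = FALSE]
    best <- pass[!duplicated(pass$protein_id), , drop = FALSE]
    fam[best$protein_id] <- best$model_id
  }
  fam
}

#' Kinase group from a family name
#'
#' The group is the family prefix before the first underscore
#' (`"RLK-Pelle_DLSV"` -> `"RLK-Pelle"`); a family without underscore is its
#' own group.
#'
#' @param family character vector of family names (NA passed through).
#' @return character vector of group names.
#' @export
kinaseGroup <- function(family) {
  ifelse(is.na(family), NA_character_, sub("_.*$", "", family))
}

#' Build a kinase catalog
#'
#' @param candidates data.frame from [identifyKinases()].
#' @param families named vector from [assignFamilies()] (proteins absent from
#'   it are unassigned).
#' @return a [KinaseCatalog-class] with all loci in status `candidate`.
#' @export
buildCatalog <- function(candidates, families) {
  fam <- unname(families[candidates$protein_id])
  tb <- data.frame(
    protein_id = candidates$protein_id,
    family = fam,
    group = kinaseGroup(fam),
    n_domains = candidates$n_kinase_domains,
    status = "candidate",
    stringsAsFactors = FALSE
  )
  tb <- tb[order(tb$protein_id), , drop = FALSE]
  rownames(tb) <- NULL
  new("KinaseCatalog", table = tb)
}

#' Tree-concordance (bona fide / UNK) filter
#'
#' Cross-validates HMM family assignments against the NJ tree: a protein whose
#' family has a single member is `bona_fide` by default; otherwise it is
#' `bona_fide` iff at least one of its `neighbor_depth` nearest other leaves
#' (patristic distance, ties broken lexicographically by leaf id) shares its
#' family. Everything else is `UNK`. An alternative interpretation
#' (`method = "clade"`) instead requires the smallest non-trivial clade
#' containing the leaf to be at least half same-family.
#'
#' @param tree `phylo` whose tips are catalog proteins.
#' @param families named character vector protein_id -> family covering every
#'   leaf.
#' @param neighbor_depth how many nearest leaves to inspect (default 1).
#' @param method `"nearest"` (default) or `"clade"`.
#' @return named character vector protein_id -> `"bona_fide"`/`"UNK"`.
#' @export
concordanceFilter <- function(tree, families, neighbor_depth = 1,
                              method = c("nearest", "clade")) {
  method <- match.arg(method)
  tips <- tree$tip.label
  if (!all(tips %in% names(families)) || any(is.na(families[tips])))
    stop("leaf without family assignment: ",
         paste(setdiff(tips, names(families)[!is.na(families)]),
               collapse = ", "))
  fam <- families[tips]
  fam_size <- table(fam)
  status <- stats::setNames(rep("UNK", length(tips)), tips)
  singles <- tips[fam_size[fam] == 1]
  status[singles] <- "bona_fide"
  multi <- setdiff(tips, singles)
  if (!length(multi)) return(status)

  if (method == "nearest") {
    D <- patristicDistances(tree)
    for (tip in multi) {
      others <- setdiff(tips, tip)
      ord <- others[order(D[tip, others], others)]
      nn <- ord[seq_len(min(neighbor_depth, length(ord)))]
      if (any(fam[nn] == fam[tip])) status[tip] <- "bona_fide"
    }
  } else {
    n <- length(tips)
    kids <- split(tree$edge[, 2], tree$edge[, 1])
    sets <- vector("list", n + tree$Nnode)
    for (i in seq_len(n)) sets[[i]] <- tips[i]
    ord <- unique(tree$edge[ape::postorder(tree), 1])
    for (nd in ord)
      sets[[nd]] <- unlist(sets[kids[[as.character(nd)]]], use.names = FALSE)
    parent <- stats::setNames(tree$edge[, 1], tree$edge[, 2])
    for (tip in multi) {
      # smallest clade containing the leaf plus at least one other leaf is the
      # clade of its parent node
      nd <- parent[[as.character(match(tip, tips))]]
      peers <- setdiff(sets[[nd]], tip)
      if (mean(fam[peers] == fam[tip]) >= 0.5) status[tip] <- "bona_fide"
    }
  }
  status
}
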