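#' Differential-expression filter
#'
#' Calls a transcript `up` when `log2FC > lfc_threshold`, `p < p_threshold`
#' and `fdr < fdr_threshold`; `down` when `log2FC < -lfc_threshold` with the
#' same p/FDR conditions; `ns` otherwise. All inequalities are strict, so a
#' transcript sitting exactly on a threshold is never called.
#'
#' @param table data.frame with columns `log2FC`, `p`, `fdr` (any id columns
#'   are carried through).
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param p_threshold p-value threshold (default 0.05).
#' @param fdr_threshold adjusted-p threshold (default 0.05).
#' @return the input with a `call` column (`up`/`down`/`ns`); the per-call
#'   counts are attached as attribute `counts`.
#' @export
deFilter <- function(table, lfc_threshold = 1, p_threshold = 0.05,
                     fdr_threshold = 0.05) {
  for (col in c("log2FC", "p", "fdr"))
    if (!col %in% colnames(table)) stop("missing column: ", col)
  sig <- table$p < p_threshold & table$fdr < fdr_threshold
  call <- ifelse(sig & table$log2FC > lfc_threshold, "up",
                 ifelse(sig & table$log2FC < -lfc_threshold, "down", "ns"))
  out <- table
  out$call <- call
  attr(out, "counts") <- c(up = sum(call == "up"), down = sum(call == "down"),
                           ns = sum(call == "ns"))
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: adjusted value
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bhFdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-family up/down-regulation tallies
#'
#' Counts distinct differentially expressed transcripts per kinase family (and
#' group) per treatment, ranked by count (descending) then family name.
#'
#' @param catalog a [KinaseCatalog-class] (or data.frame with `protein_id`,
#'   `family`, `group`).
#' @param de_records data.frame with `transcript_id`, `treatment`, `call`
#'   columns (e.g. output of [deFilter()] plus ids).
#' @param direction which calls to tally (default `"up"`).
#' @return data.frame `family`, `group`, `treatment`, `n`; transcripts absent
#'   from the catalog are returned in the `unmapped` attribute.
#' @export
familyTally <- function(catalog, de_records, direction = "up") {
  tb <- if (is(catalog, "KinaseCatalog")) catalogTable(catalog) else catalog
  de <- de_records[de_records$call == direction, , drop = FALSE]
  de <- de[!duplicated(de[, c("transcript_id", "treatment")]), , drop = FALSE]
  idx <- match(de$transcript_id, tb$protein_id)
  unmapped <- unique(de$transcript_id[is.na(idx)])
  de <- de[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (!nrow(de)) {
    out <- data.frame(family = character(0), group = character(0),
                      treatment = character(0), n = integer(0))
  } else {
    agg <- stats::aggregate(
      list(n = de$transcript_id),
      by = list(family = tb$family[idx], treatment = de$treatment),
      FUN = function(x) length(unique(x)))
    agg$group <- kinaseGroup(agg$family)
    out <- agg[order(-agg$n, agg$family, agg$treatment),
               c("family", "group", "treatment", "n")]
    rownames(out) <- NULL
  }
  attr(out, "unmapped") <- unmapped
  out
}

#' Crosstalk transcripts across assays
#'
#' Transcripts up-regulated in every assay (plus all pairwise intersections).
#'
#' @param up_sets named list (>= 2 entries), assay -> character vector of
#'   up-regulated transcript ids.
#' @param families optional named vector transcript -> family.
#' @return list with `shared` (ids in all assays), `families` (their
#'   families, if supplied) and `pairwise` (data.frame assayA, assayB, n,
#'   ids).
#' @export
crosstalk <- function(up_sets, families = NULL) {
  if (length(up_sets) < 2) stop("need at least two assays")
  shared <- sort(Reduce(intersect, up_sets))
  combs <- utils::combn(names(up_sets), 2)
  pw <- apply(combs, 2, function(ab) {
    ids <- sort(intersect(up_sets[[ab[1]]], up_sets[[ab[2]]]))
    data.frame(assayA = ab[1], assayB = ab[2], n = length(ids),
               ids = paste(ids, collapse = ","), stringsAsFactors = FALSE)
  })
  list(shared = shared,
       families = if (!is.null(families)) unique(unname(families[shared])),
       pairwise = do.call(rbind, pw))
}

#' Hypergeometric GO-term enrichment
#'
#' For each term annotating at least one foreground gene, the upper-tail
#' hypergeometric p-value of the foreground count given the background, with
#' Benjamini-Hochberg correction across tested terms. A term is enriched when
#' `p < p_cutoff` and `fdr < fdr_cutoff` (strict).
#'
#' @param foreground character vector of genes of interest.
#' @param background character vector containing every foreground gene (the
#'   assay's whole transcriptome).
#' @param annotations data.frame with columns `gene`, `term` and optionally
#'   `name`.
#' @param p_cutoff,fdr_cutoff strict enrichment cutoffs (default 0.05 each).
#' @return data.frame `term`, `name`, `k`, `n`, `K`, `N`, `p`, `fdr`,
#'   `enriched`, ordered by p.
#' @export
goEnrichment <- function(foreground, background, annotations,
                         p_cutoff = 0.05, fdr_cutoff = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground gene absent from background: ",
         paste(setdiff(foreground, background)[1:3], collapse = ", "))
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  ann <- ann[!duplicated(ann[, c("gene", "term")]), , drop = FALSE]
  N <- length(background)
  n <- length(foreground)
  terms <- split(ann$gene, ann$term)
  names_map <- if ("name" %in% colnames(ann))
    stats::setNames(ann$name, ann$term) else NULL
  rows <- lapply(names(terms), function(tm) {
    genes <- terms[[tm]]
    k <- sum(foreground %in% genes)
    if (k == 0) return(NULL)
    K <- length(genes)
    data.frame(term = tm,
               name = if (!is.null(names_map)) names_map[[tm]] else tm,
               k = k, n = n, K = K, N = N,
               p = hypergeomTail(k, N, K, n), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(0), name = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p = numeric(0), fdr = numeric(0), enriched = logical(0)))
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$p)
  out$enriched <- out$p < p_cutoff & out$fdr < fdr_cutoff
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ratio for one allocation: ct values per gene, logical control mask per gene
.restRatioFromCt <- function(ct_target, ctl_target, ct_refs, ctl_refs,
                             E_target, E_refs) {
  dct_t <- mean(ct_target[ctl_target]) - mean(ct_target[!ctl_target])
  num <- E_target^dct_t
  den <- vapply(seq_along(ct_refs), function(g) {
    dct <- mean(ct_refs[[g]][ctl_refs[[g]]]) - mean(ct_refs[[g]][!ctl_refs[[g]]])
    E_refs[g]^dct
  }, numeric(1))
  num / exp(mean(log(den)))
}

#' qPCR relative expression with a randomization test
#'
#' Efficiency-corrected relative expression of a target gene against one or
#' more reference genes (Pfaffl model):
#' `ratio = E_target^dCt_target / geomean_g(E_g^dCt_g)` with
#' `dCt = mean(control Ct) - mean(treated Ct)`. Significance is assessed by a
#' fixed-reallocation randomization test: control/treated labels are reshuffled
#' (jointly across target and reference genes when all share the same
#' replicate structure, independently per gene otherwise) and the two-sided
#' p-value is the proportion of reallocations whose ratio is at least as far
#' from 1 on the log scale as the observed ratio. All distinct reallocations
#' are enumerated when there are at most `n_permutations` of them; otherwise
#' `n_permutations` random reallocations are drawn and the p-value includes
#' the observed allocation (add-one correction).
#'
#' @param ct_control_target,ct_treated_target numeric Ct vectors (>= 2
#'   replicates each).
#' @param ct_control_refs,ct_treated_refs list of numeric Ct vectors, one per
#'   reference gene.
#' @param E_target amplification efficiency of the target, fold per cycle
#'   (2.0 = 100%); percent efficiencies convert as `E = 1 + pct/100`.
#' @param E_refs efficiencies of the reference genes.
#' @param n_permutations randomization budget (default 2000).
#' @param seed integer seed for the sampled case.
#' @return data.frame `ratio`, `delta_ct_target`, `p_random`, `n_reallocations`,
#'   `exhaustive`.
#' @export
restRatio <- function(ct_control_target, ct_treated_target,
                      ct_control_refs, ct_treated_refs,
                      E_target = 2, E_refs = rep(2, length(ct_control_refs)),
                      n_permutations = 2000, seed = NULL) {
  if (!is.list(ct_control_refs)) ct_control_refs <- list(ct_control_refs)
  if (!is.list(ct_treated_refs)) ct_treated_refs <- list(ct_treated_refs)
  if (any(c(E_target, E_refs) <= 1))
    stop("amplification efficiencies must exceed 1 (fold per cycle)")
  if (length(ct_control_target) < 2 || length(ct_treated_target) < 2)
    stop("need at least two replicates per group")
  nrefs <- length(ct_control_refs)
  stopifnot(length(ct_treated_refs) == nrefs, length(E_refs) == nrefs)

  ct_t <- c(ct_control_target, ct_treated_target)
  nc_t <- length(ct_control_target)
  ctl_t <- seq_along(ct_t) <= nc_t
  ct_r <- vector("list", nrefs); ctl_r <- vector("list", nrefs)
  nc_r <- integer(nrefs)
  for (g in seq_len(nrefs)) {
    ct_r[[g]] <- c(ct_control_refs[[g]], ct_treated_refs[[g]])
    nc_r[g] <- length(ct_control_refs[[g]])
    ctl_r[[g]] <- seq_along(ct_r[[g]]) <= nc_r[g]
  }

  obs <- .restRatioFromCt(ct_t, ctl_t, ct_r, ctl_r, E_target, E_refs)
  obs_stat <- abs(log(obs))
  dct_t <- mean(ct_t[ctl_t]) - mean(ct_t[!ctl_t])

  same_structure <- all(vapply(ct_r, length, integer(1)) == length(ct_t)) &&
    all(nc_r == nc_t)
  joint_total <- choose(length(ct_t), nc_t)

  stats_perm <- NULL
  if (same_structure && joint_total <= n_permutations) {
    combos <- utils::combn(length(ct_t), nc_t)
    stats_perm <- apply(combos, 2, function(ctl_idx) {
      mask <- seq_along(ct_t) %in% ctl_idx
      masks <- rep(list(mask), nrefs)
      abs(log(.restRatioFromCt(ct_t, mask, ct_r, masks, E_target, E_refs)))
    })
    exhaustive <- TRUE
    n_used <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_perm <- vapply(seq_len(n_permutations), function(b) {
      mask_t <- seq_along(ct_t) %in% sample(length(ct_t), nc_t)
      masks <- if (same_structure) rep(list(mask_t), nrefs)
      else lapply(seq_len(nrefs), function(g)
        seq_along(ct_r[[g]]) %in% sample(length(ct_r[[g]]), nc_r[g]))
      abs(log(.restRatioFromCt(ct_t, mask_t, ct_r, masks, E_target, E_refs)))
    }, numeric(1))
    exhaustive <- FALSE
    n_used <- n_permutations
  }
  tol <- 1e-12
  if (exhaustive) {
    p <- mean(stats_perm >= obs_stat - tol)
  } else {
    p <- (sum(stats_perm >= obs_stat - tol) + 1) / (n_used + 1)
  }
  data.frame(ratio = obs, delta_ct_target = dct_t, p_random = p,
             n_reallocations = n_used, exhaustive = exhaustive)
}
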