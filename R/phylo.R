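#' Pairwise p-distance matrix from a multiple alignment
#'
#' Proportion of mismatching positions per pair, comparing only columns where
#' neither sequence has a gap (`-` or `.`): pairwise deletion.
#'
#' @param msa named character vector of equal-length aligned sequences, or an
#'   `XStringSet`.
#' @return symmetric numeric matrix with sequence names as dimnames.
#' @export
pDistanceMatrix <- function(msa) {
  msa <- stats::setNames(as.character(msa), names(msa))
  if (is.null(names(msa)) || anyDuplicated(names(msa)))
    stop("alignment sequences must have unique names")
  if (length(unique(nchar(msa))) != 1L)
    stop("aligned sequences must have equal length")
  n <- length(msa)
  M <- do.call(rbind, strsplit(toupper(msa), ""))
  gap <- M == "-" | M == "."
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop("no comparable columns between ", names(msa)[i], " and ",
             names(msa)[j])
      d <- sum(M[i, comp] != M[j, comp]) / nc
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q-criterion. Ties in the Q minimum are
#' broken by the lexicographically smallest pair of cluster labels (a cluster
#' is labeled by its smallest leaf), so the output is deterministic. Negative
#' branch-length estimates are clamped to zero. The result is an unrooted
#' binary `phylo` tree (basal trifurcation).
#'
#' @param D symmetric, non-negative distance matrix with unique dimnames,
#'   >= 3 taxa.
#' @return an [ape::read.tree()]-style `phylo` object.
#' @export
njTree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  if (any(is.na(D)) || any(!is.finite(D)))
    stop("D contains NA/NaN/Inf")
  if (max(abs(D - t(D))) > 1e-9)
    stop("D is not symmetric")
  labels <- rownames(D)
  if (is.null(labels) || anyDuplicated(labels))
    stop("D needs unique dimnames")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")

  node_id <- seq_len(n)          # ape tip numbers
  rep_lab <- labels              # cluster representative = smallest leaf label
  next_internal <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  W <- D

  while (length(node_id) > 3) {
    m <- length(node_id)
    r <- rowSums(W)
    Q <- (m - 2) * W - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- W[i, j]
    li <- max(0, dij / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- max(0, dij - li)
    new_id <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(new_id, node_id[i]), c(new_id, node_id[j]))
    lens <- c(lens, li, lj)
    dk <- pmax(0, (W[i, ] + W[j, ] - dij) / 2)[-c(i, j)]
    keep <- setdiff(seq_len(m), c(i, j))
    W <- W[keep, keep, drop = FALSE]
    W <- rbind(cbind(W, dk), c(dk, 0))
    new_lab <- min(rep_lab[c(i, j)])
    rep_lab <- c(rep_lab[keep], new_lab)
    node_id <- c(node_id[keep], new_id)
  }

  # final trifurcation: closed-form three-taxon branch lengths
  d12 <- W[1, 2]; d13 <- W[1, 3]; d23 <- W[2, 3]
  l1 <- max(0, (d12 + d13 - d23) / 2)
  l2 <- max(0, (d12 + d23 - d13) / 2)
  l3 <- max(0, (d13 + d23 - d12) / 2)
  root <- next_internal
  edges <- rbind(edges, c(root, node_id[1]), c(root, node_id[2]),
                 c(root, node_id[3]))
  lens <- c(lens, l1, l2, l3)

  # ape numbering: root must be n+1; renumber internal nodes
  internal_old <- c(root, setdiff(sort(unique(edges[edges > n])), root))
  remap <- stats::setNames(seq(n + 1L, n + length(internal_old)), internal_old)
  e <- edges
  e[e > n] <- remap[as.character(e[e > n])]
  tree <- list(edge = e, edge.length = lens, tip.label = labels,
               Nnode = length(internal_old))
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

# tip-label sets below each internal node (excluding the root's full set);
# keys canonicalized so a bipartition has one name regardless of side
.treeSplits <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  ord <- unique(tree$edge[ape::postorder(tree), 1]) # children before parents
  for (nd in ord) {
    sets[[nd]] <- sort(unlist(sets[kids[[as.character(nd)]]], use.names = FALSE))
  }
  all_tips <- sort(tree$tip.label)
  first <- all_tips[1]
  keys <- character(0)
  nodes <- integer(0)
  for (nd in seq(n + 2L, n + nn)) { # skip the root (n+1): trivial split
    s <- sets[[nd]]
    if (length(s) < 2 || length(s) > n - 2) next
    if (first %in% s) s <- setdiff(all_tips, s)
    keys <- c(keys, paste(s, collapse = "|"))
    nodes <- c(nodes, nd)
  }
  data.frame(node = nodes, split = keys, stringsAsFactors = FALSE)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicate trees containing the same bipartition.
#'
#' @param msa named character vector (or `XStringSet`) of aligned sequences.
#' @param n_replicates bootstrap replicates (the study default is 1000).
#' @param seed integer seed; fixed seed gives identical supports.
#' @param dist_fun distance function applied to each resampled alignment.
#' @return list with `tree` (the full-data NJ `phylo`, `node.label` carrying
#'   support percentages for internal nodes, `NA` for the root) and `support`
#'   (data.frame: split key, support percentage). With fewer than 4 taxa the
#'   support table is empty and the tree carries no labels.
#' @export
bootstrapSupport <- function(msa, n_replicates = 1000, seed = NULL,
                             dist_fun = pDistanceMatrix) {
  msa <- stats::setNames(as.character(msa), names(msa))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tree <- njTree(dist_fun(msa))
  n <- length(msa)
  if (n < 4)
    return(list(tree = tree, support = data.frame(split = character(0),
                                                  support = numeric(0))))
  L <- nchar(msa[[1]])
  chars <- do.call(rbind, strsplit(msa, ""))
  orig <- .treeSplits(tree)
  counts <- stats::setNames(numeric(nrow(orig)), orig$split)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_msa <- stats::setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                                     collapse = ""), names(msa))
    rep_tree <- njTree(dist_fun(rep_msa))
    hits <- intersect(.treeSplits(rep_tree)$split, orig$split)
    counts[hits] <- counts[hits] + 1
  }
  support <- 100 * counts / n_replicates
  lab <- rep(NA_real_, tree$Nnode)
  lab[orig$node - n] <- support[orig$split]
  tree$node.label <- as.character(ifelse(is.na(lab), "", round(lab, 1)))
  list(tree = tree,
       support = data.frame(split = orig$split, support = unname(support),
                            stringsAsFactors = FALSE))
}

#' Patristic (path-length) distances between tree leaves
#'
#' @param tree a `phylo` object with non-negative branch lengths.
#' @return symmetric matrix of leaf-to-leaf path lengths.
#' @export
patristicDistances <- function(tree) {
  n <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}
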