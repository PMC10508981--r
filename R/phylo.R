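# Distance phylogenetics with bootstrap support, credibility filtering, and
# Fitch parsimony. Neighbor-joining + Felsenstein bootstrap replaces the
# maximum-likelihood machinery of large-scale analyses while keeping the same
# downstream decision semantics (credible clusters at a support threshold,
# monophyly tests, two-of-three lineage removal).

GAPCHARS <- c("-", ".")

#' Percent identity of two aligned rows
#'
#' `100 * matches / columns where neither row is a gap`; 0 when no such
#' columns exist.
#'
#' @param a,b equal-length gapped amino-acid strings.
#' @return percent identity.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop_parameter("aligned rows differ in length")
  va <- chars(a); vb <- chars(b)
  ok <- !(va %in% GAPCHARS) & !(vb %in% GAPCHARS)
  if (!any(ok)) return(0)
  100 * sum(va[ok] == vb[ok]) / sum(ok)
}

# p-distances on a character matrix (rows = sequences)
.pdist <- function(m, labels) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  gap <- matrix(m %in% GAPCHARS, nrow = n)
  zero_pairs <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) {
      d[i, j] <- d[j, i] <- NA_real_
      zero_pairs <- TRUE
    } else {
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      d[i, j] <- d[j, i] <- p
    }
  }
  if (zero_pairs) {
    mx <- max(d, na.rm = TRUE)
    warning("pair(s) with zero comparable columns; distance set to max + 0.1")
    d[is.na(d)] <- mx + 0.1
    diag(d) <- 0
  }
  d
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
}

#' Pairwise distance matrix from an alignment
#'
#' p-distance (1 - identity/100) by default; an optional Poisson correction
#' `-ln(1 - p)` is available.
#'
#' @param aln named character vector of equal-length aligned rows.
#' @param correction `"none"` (p-distance) or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  if (length(aln) < 3) stop_parameter("need at least 3 sequences")
  if (length(unique(nchar(aln))) != 1) stop_parameter("ragged alignment")
  d <- .pdist(aln_matrix(aln), names(aln))
  if (correction == "poisson") d <- -log(1 - pmin(d, 0.999))
  d
}

fmt_bl <- function(x) sprintf("%.12g", max(0, x))

#' Neighbor-joining tree
#'
#' Canonical neighbor joining (Q-matrix criterion, standard branch-length
#' formulas), negative branch lengths clamped to zero, ties in the Q matrix
#' broken by the lexicographically smallest taxon pair. The result is the
#' usual unrooted tree with a basal trifurcation.
#'
#' @param d symmetric distance matrix with row/column names.
#' @return an [ape::read.tree()] `phylo` object (supports unset).
#' @export
nj_tree <- function(d) {
  D <- as.matrix(d)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop_parameter("distance matrix must be symmetric")
  if (nrow(D) < 3) stop_parameter("need at least 3 taxa")
  nwk <- rownames(D)
  rep_lab <- rownames(D)  # smallest tip label in each subtree, for tie-breaks
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(p) {
      pr <- sort(c(rep_lab[p[1]], rep_lab[p[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    ks <- setdiff(seq_len(n), c(i, j))
    dnew <- (D[i, ks] + D[j, ks] - D[i, j]) / 2
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt_bl(vi), nwk[j], fmt_bl(vj))
    new_rep <- min(rep_lab[i], rep_lab[j])
    D <- rbind(cbind(D[ks, ks, drop = FALSE], dnew), c(dnew, 0))
    nwk <- c(nwk[ks], new_nwk)
    rep_lab <- c(rep_lab[ks], new_rep)
    rownames(D) <- colnames(D) <- paste0("n", seq_len(nrow(D)))
  }
  x <- D[1, 2]; y <- D[1, 3]; z <- D[2, 3]
  v1 <- (x + y - z) / 2
  v2 <- (x + z - y) / 2
  v3 <- (y + z - x) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt_bl(v1),
                 nwk[2], fmt_bl(v2), nwk[3], fmt_bl(v3))
  ape::read.tree(text = txt)
}

# tip label sets for every node (index = ape node id)
clade_tipsets <- function(tree) {
  nt <- length(tree$tip.label)
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; c <- tr$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

canonical_split <- function(tips, all_tips) {
  tips <- sort(tips)
  if (min(all_tips) %in% tips) tips <- sort(setdiff(all_tips, tips))
  paste(tips, collapse = "|")
}

# canonical keys of the non-trivial bipartitions, named by internal node id
tree_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  sets <- clade_tipsets(tree)
  root <- nt + 1L
  ids <- setdiff(seq_len(nt + tree$Nnode), c(seq_len(nt), root))
  keys <- vapply(ids, function(i) {
    s <- sets[[i]]
    if (length(s) <= 1 || length(s) >= nt - 1) return(NA_character_)
    canonical_split(s, all_tips)
  }, character(1))
  names(keys) <- ids
  keys[!is.na(keys)]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Felsenstein bootstrap: alignment columns are resampled with replacement,
#' a tree is built per replicate (p-distance + NJ), and each internal
#' bipartition of the full-data tree is annotated with the percentage of
#' replicates containing it (stored in `node.label`).
#'
#' @param aln named character vector of aligned rows.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed for the resampling.
#' @return the full-data `phylo` tree with supports in `node.label`.
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1L) {
  if (n_reps < 1) stop_parameter("n_reps must be >= 1")
  m <- aln_matrix(aln)
  labels <- names(aln)
  full <- nj_tree(.pdist(m, labels))
  keys <- tree_bipartitions(full)
  counts <- stats::setNames(rep(0, length(keys)), keys)
  L <- ncol(m)
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      tr <- suppressWarnings(nj_tree(.pdist(m[, cols, drop = FALSE], labels)))
      for (k in unique(tree_bipartitions(tr))) {
        if (k %in% names(counts)) counts[k] <- counts[k] + 1
      }
    }
  })
  supp <- round(100 * counts / n_reps, 1)
  nt <- length(full$tip.label)
  lab <- rep("", full$Nnode)
  ids <- as.integer(names(keys))
  lab[ids - nt] <- as.character(supp[keys])
  full$node.label <- lab
  full
}

node_supports <- function(tree) {
  if (is.null(tree$node.label)) stop_parameter("tree carries no supports")
  suppressWarnings(as.numeric(tree$node.label))
}

#' Credible clusters of a supported tree
#'
#' Bipartitions whose support meets the threshold, reported as the tip set of
#' the smaller side.
#'
#' @param tree a `phylo` with supports in `node.label`.
#' @param threshold support threshold, percent (inclusive).
#' @return list of character vectors of tip labels.
#' @export
credible_clusters <- function(tree, threshold = 95) {
  supp <- node_supports(tree)
  nt <- length(tree$tip.label)
  sets <- clade_tipsets(tree)
  keys <- tree_bipartitions(tree)
  out <- list()
  for (id in as.integer(names(keys))) {
    s <- supp[id - nt]
    if (is.na(s) || s < threshold) next
    cl <- sort(sets[[id]])
    other <- sort(setdiff(tree$tip.label, cl))
    out[[length(out) + 1L]] <- if (length(other) < length(cl)) other else cl
  }
  out
}

#' Test monophyly of a tip set
#'
#' TRUE iff some edge of the (unrooted) tree splits exactly `tips` from the
#' rest; when the tree carries supports, the defining edge's support is
#' returned too.
#'
#' @param tree a `phylo`.
#' @param tips character vector, a proper non-empty subset of the tips.
#' @return list with `monophyletic` and `support` (NA when unsupported or
#'   when the split is trivial).
#' @export
test_monophyly <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label))
    stop_parameter("tips not all present in the tree")
  nt <- length(tree$tip.label)
  if (length(tips) == 0 || length(tips) >= nt)
    stop_parameter("tips must be a proper non-empty subset")
  if (length(tips) == 1 || length(tips) == nt - 1)
    return(list(monophyletic = TRUE, support = NA_real_))
  key <- canonical_split(tips, sort(tree$tip.label))
  keys <- tree_bipartitions(tree)
  hit <- names(keys)[keys == key]
  if (length(hit) == 0) return(list(monophyletic = FALSE, support = NA_real_))
  supp <- if (is.null(tree$node.label)) NA_real_
          else node_supports(tree)[as.integer(hit[1]) - nt]
  list(monophyletic = TRUE, support = supp)
}

#' Concatenate two alignments on shared ids
#'
#' @param a1,a2 named character vectors of aligned rows.
#' @return named character vector over the id intersection, rows pasted;
#'   the first partition's width is attached as attribute `"partition"`.
#' @export
concat_alignment <- function(a1, a2) {
  ids <- intersect(names(a1), names(a2))
  if (length(ids) == 0) stop_parameter("alignments share no ids")
  out <- stats::setNames(paste0(a1[ids], a2[ids]), ids)
  attr(out, "partition") <- nchar(a1[[1]])
  out
}

#' Progressive multiple alignment
#'
#' Guide tree from 3-mer set distances (average-linkage clustering), then
#' progressive profile-profile Needleman-Wunsch merging with BLOSUM62 column
#' scores and a linear gap penalty. Fully deterministic.
#'
#' @param seqs named character vector of (ungapped) amino-acid sequences.
#' @param gap linear gap penalty.
#' @return named character vector of equal-length aligned rows, input order.
#' @export
progressive_align <- function(seqs, gap = -4) {
  n <- length(seqs)
  if (n < 2) stop_parameter("need at least 2 sequences")
  ids <- names(seqs)
  if (is.null(ids)) ids <- names(seqs) <- paste0("s", seq_len(n))
  if (n == 2) {
    al <- align_pair(seqs[[1]], seqs[[2]], gap = gap)
    return(stats::setNames(c(al[1], al[2]), ids))
  }
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < 3) return(s)
    unique(substring(s, 1:(nchar(s) - 2), 3:nchar(s)))
  })
  kd <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(kmers[[i]], kmers[[j]]))
    kd[i, j] <- kd[j, i] <-
      1 - shared / max(1, min(length(kmers[[i]]), length(kmers[[j]])))
  }
  hc <- stats::hclust(stats::as.dist(kd), method = "average")
  # BLOSUM62 extended with a gap row/column (residue-gap = gap penalty)
  ext <- rbind(cbind(blosum62(), `-` = gap), `-` = c(rep(gap, 20), 0))
  to_counts <- function(mat) {
    apply(mat, 2, function(col) {
      col[!col %in% AA20] <- "-"
      tabulate(match(col, c(AA20, "-")), nbins = 21)
    })
  }
  profiles <- vector("list", n)  # merge-node profiles: char matrices
  leaves <- lapply(seqs, function(s) matrix(chars(s), nrow = 1))
  members <- vector("list", n)
  get_prof <- function(k) if (k < 0) leaves[[-k]] else profiles[[k]]
  get_mem <- function(k) if (k < 0) ids[-k] else members[[k]]
  for (m in seq_len(nrow(hc$merge))) {
    A <- get_prof(hc$merge[m, 1]); B <- get_prof(hc$merge[m, 2])
    CA <- to_counts(A); CB <- to_counts(B)
    S <- (t(CA) %*% ext %*% CB) / (nrow(A) * nrow(B))
    r <- nw_core(S, gap)
    ncol_new <- length(r$ai)
    out <- matrix("-", nrow(A) + nrow(B), ncol_new)
    ia <- which(!is.na(r$ai)); ib <- which(!is.na(r$bj))
    out[seq_len(nrow(A)), ia] <- A[, r$ai[ia], drop = FALSE]
    out[nrow(A) + seq_len(nrow(B)), ib] <- B[, r$bj[ib], drop = FALSE]
    profiles[[m]] <- out
    members[[m]] <- c(get_mem(hc$merge[m, 1]), get_mem(hc$merge[m, 2]))
  }
  final <- profiles[[nrow(hc$merge)]]
  rows <- apply(final, 1, paste, collapse = "")
  stats::setNames(rows[match(ids, members[[nrow(hc$merge)]])], ids)
}

#' Compute lineage credibility flags
#'
#' Criterion 1: the lineage falls in no credible cluster together with
#' another lineage from its own taxon group. Criterion 2: its structure label
#' occurs exactly once in the cohort. Criterion 3: the element occupies a
#' whole contig and/or lacks predicted LTRs (from the miner's flags).
#'
#' @param lineages data.frame with columns `lineage`, `taxon_group`,
#'   `structure`, `whole_contig_or_no_ltr`.
#' @param clusters list of credible-cluster tip sets (lineage ids), e.g. from
#'   [credible_clusters()].
#' @return data.frame of `LineageFlags`: `lineage`, `c1_discordant_clustering`,
#'   `c2_unique_structure`, `c3_whole_contig_or_no_ltr`.
#' @export
lineage_flags <- function(lineages, clusters) {
  structure_counts <- table(lineages$structure)
  c1 <- vapply(seq_len(nrow(lineages)), function(i) {
    id <- lineages$lineage[i]
    grp <- lineages$lineage[lineages$taxon_group == lineages$taxon_group[i]]
    grp <- setdiff(grp, id)
    if (length(grp) == 0) return(TRUE)
    !any(vapply(clusters, function(cl) id %in% cl && any(grp %in% cl),
                logical(1)))
  }, logical(1))
  data.frame(lineage = lineages$lineage,
             c1_discordant_clustering = c1,
             c2_unique_structure =
               as.integer(structure_counts[lineages$structure]) == 1L,
             c3_whole_contig_or_no_ltr =
               as.logical(lineages$whole_contig_or_no_ltr),
             stringsAsFactors = FALSE)
}

#' Apply the two-of-three lineage filter
#'
#' A lineage is removed iff at least two of its three flags are true.
#'
#' @param flags data.frame with columns `lineage`,
#'   `c1_discordant_clustering`, `c2_unique_structure`,
#'   `c3_whole_contig_or_no_ltr`.
#' @return list with `flags` (input plus `removed`), `retained` and
#'   `removed` lineage id vectors.
#' @export
filter_lineages <- function(flags) {
  k <- flags$c1_discordant_clustering + flags$c2_unique_structure +
    flags$c3_whole_contig_or_no_ltr
  flags$removed <- k >= 2
  list(flags = flags,
       retained = flags$lineage[!flags$removed],
       removed = flags$lineage[flags$removed])
}

#' Fitch parsimony on a rooted binary tree
#'
#' Bottom-up intersection/union over state sets, generalized to multi-state
#' (polymorphic) tips; returns the minimum number of state changes and the
#' per-node Fitch state sets.
#'
#' @param species_tree a rooted, binary `phylo`.
#' @param tip_states named list: tip label -> non-empty character vector of
#'   structure labels.
#' @return list with `changes` and `states` (list over tips then internal
#'   nodes, named by tip label / `node<N>`).
#' @export
fitch_parsimony <- function(species_tree, tip_states) {
  tr <- species_tree
  if (!ape::is.rooted(tr) || !ape::is.binary(tr))
    stop_parameter("species tree must be rooted and binary")
  nt <- length(tr$tip.label)
  missing_tips <- setdiff(tr$tip.label, names(tip_states))
  if (length(missing_tips) > 0)
    stop_parameter(paste("tips without states:",
                         paste(missing_tips, collapse = ", ")))
  if (any(vapply(tip_states[tr$tip.label], length, integer(1)) == 0))
    stop_parameter("every tip needs at least one state")
  sets <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- unique(tip_states[[tr$tip.label[i]]])
  changes <- 0L
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  root <- nt + 1L
  # explicit-stack postorder so children are always resolved before parents
  stack <- c(root)
  order_out <- integer(0)
  while (length(stack) > 0) {
    p <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_out <- c(p, order_out)
    ch <- kids[[as.character(p)]]
    stack <- c(stack, ch[ch > nt])
  }
  for (p in order_out) {
    ch <- kids[[as.character(p)]]
    s <- Reduce(intersect, sets[ch])
    if (length(s) == 0) {
      s <- Reduce(union, sets[ch])
      changes <- changes + 1L
    }
    sets[[p]] <- sort(s)
  }
  names(sets) <- c(tr$tip.label, paste0("node", nt + seq_len(tr$Nnode)))
  list(changes = changes, states = sets)
}
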