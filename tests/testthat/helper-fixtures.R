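# Shared fixtures and independent oracles. Everything is generated in code;
# expensive fixtures (a mined six-structure genome) are built once per run.

.fx <- new.env(parent = emptyenv())

fixture_library <- function() {
  if (is.null(.fx$lib)) .fx$lib <- make_profile_library(42)
  .fx$lib
}

fixture_profiles <- function() {
  if (is.null(.fx$prof))
    .fx$prof <- profiles_from_specs(fixture_library(), seed = 7)
  .fx$prof
}

six_labels <- c("S1", "S2", "S3", "S4", "S5", "NO_ARH")

make_blueprints <- function(labels, ltr_div = 0, dom_div = 0,
                            degrade = TRUE, seed0 = 100) {
  lapply(seq_along(labels), function(i)
    element_blueprint(labels[i], ltr_divergence = ltr_div,
                      domain_divergence = dom_div,
                      degrade_native_rh = degrade && labels[i] != "NO_ARH",
                      degrade_distal_arh = degrade && labels[i] == "S5",
                      seed = seed0 + i))
}

# one noise-free six-structure genome, mined and ORF-assigned; cached because
# several test files exercise different stages on the same recovery problem
fixture_mined <- function() {
  if (is.null(.fx$mined)) {
    lib <- fixture_library()
    sim <- plant_elements(150000, make_blueprints(six_labels), lib,
                          seed = 11, min_gap = 12000, margin = 6000)
    mined <- mine_genome(sim$genome, fixture_profiles())
    chains <- lapply(mined$chains, assign_orfs, genome = sim$genome)
    .fx$mined <- list(sim = sim, hits = mined$hits, chains = chains)
  }
  .fx$mined
}

# construct an element_chain directly (classification-rule unit tests)
make_chain <- function(domains, orfs, strand = "+", start0 = 1000,
                       step = 700, width = 390, genome = "g1",
                       aaseq = NULL) {
  k <- length(domains)
  starts <- start0 + step * (0:(k - 1))
  if (strand == "-") starts <- rev(starts)  # element order = descending starts
  h <- data.frame(domain = domains, genome = genome, strand = strand,
                  start = starts, end = starts + width, frame = 1L,
                  score = 100, aaseq = if (is.null(aaseq)) strrep("A", 130)
                                       else aaseq,
                  orf = as.integer(orfs), stringsAsFactors = FALSE)
  retrotether:::new_element_chain("chain1", genome, strand, h)
}

# ---- independent oracles -------------------------------------------------

# all-offsets PSSM scan (no vectorization shortcuts)
naive_scan_scores <- function(aa, profile) {
  L <- nrow(profile$matrix)
  v <- strsplit(aa, "")[[1]]
  n <- length(v)
  if (n < L) return(numeric(0))
  AA <- colnames(profile$matrix)
  sapply(1:(n - L + 1), function(o) {
    w <- v[o:(o + L - 1)]
    if (any(!w %in% AA)) return(-Inf)
    sum(profile$matrix[cbind(1:L, match(w, AA))])
  })
}

# plain quadratic Needleman-Wunsch score, position-specific scores S, linear gap
nw_score_oracle <- function(S, gap) {
  L <- nrow(S); M <- ncol(S)
  H <- matrix(0, L + 1, M + 1)
  H[1, ] <- gap * (0:M); H[, 1] <- gap * (0:L)
  for (i in 1:L) for (j in 1:M)
    H[i + 1, j + 1] <- max(H[i, j] + S[i, j], H[i, j + 1] + gap,
                           H[i + 1, j] + gap)
  H[L + 1, M + 1]
}

profile_score_matrix <- function(seq, profile) {
  v <- strsplit(seq, "")[[1]]
  AA <- colnames(profile$matrix)
  S <- matrix(0, nrow(profile$matrix), length(v))
  ok <- which(v %in% AA)
  S[, ok] <- profile$matrix[, match(v[ok], AA), drop = FALSE]
  S
}

# exhaustive minimum-change count over all internal labelings of a rooted
# tree; a tip edge costs 0 iff the parent's state is in the tip's state set
# (the polymorphic-tip convention), so tips need not be enumerated
fitch_oracle <- function(tree, tip_states) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  labels <- sort(unique(unlist(tip_states)))
  grid <- do.call(expand.grid,
                  c(rep(list(labels), nn), stringsAsFactors = FALSE))
  tip_edge <- tree$edge[, 2] <= nt
  best <- Inf
  for (gi in seq_len(nrow(grid))) {
    internal <- as.character(grid[gi, ])
    st <- function(node) internal[node - nt]
    changes <- 0L
    for (k in seq_len(nrow(tree$edge))) {
      p <- st(tree$edge[k, 1])
      if (tip_edge[k]) {
        tip <- tree$tip.label[tree$edge[k, 2]]
        changes <- changes + as.integer(!p %in% tip_states[[tip]])
      } else {
        changes <- changes + as.integer(p != st(tree$edge[k, 2]))
      }
    }
    if (changes < best) best <- changes
  }
  best
}

# random tree with strictly positive branch lengths -> additive matrix
random_additive <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
    tr
  })
}

# simulate an alignment down a 2-clade tree: two diverged ancestors, small
# within-clade noise; returns list(aln, clade1 = ids)
two_clade_alignment <- function(n_per = 5, len = 150, seed = 1) {
  withr::with_seed(seed, {
    anc1 <- paste(sample(retrotether:::AA20, len, TRUE), collapse = "")
    anc2 <- retrotether:::.mutate_protein(anc1, 0.5)
    rows <- c(
      stats::setNames(vapply(1:n_per, function(i)
        retrotether:::.mutate_protein(anc1, 0.05), character(1)),
        paste0("a", 1:n_per)),
      stats::setNames(vapply(1:n_per, function(i)
        retrotether:::.mutate_protein(anc2, 0.05), character(1)),
        paste0("b", 1:n_per)))
    list(aln = rows, clade1 = paste0("a", 1:n_per))
  })
}

# match mined chains to planted truth records by span overlap
match_chains_to_truth <- function(chains, truth) {
  lapply(truth, function(t) {
    ovl <- vapply(chains, function(ch)
      max(0, min(ch$span[2], t$span[2]) - max(ch$span[1], t$span[1])),
      numeric(1))
    if (length(ovl) == 0 || max(ovl) == 0) NULL else chains[[which.max(ovl)]]
  })
}
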