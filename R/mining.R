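# Element recovery: six-frame PSSM scanning, hit chaining, LTR detection,
# completeness scoring, RT preclustering.

new_element_chain <- function(id, genome_id, strand, hits) {
  structure(list(id = id, genome = genome_id, strand = strand, hits = hits,
                 span = c(min(hits$start), max(hits$end)),
                 ltr = NULL, edge_truncated = FALSE, completeness = NA_real_,
                 orf_spans = NULL),
            class = "element_chain")
}

#' @export
print.element_chain <- function(x, ...) {
  cat(sprintf("<element_chain %s %s:%d-%d (%s) [%s]%s>\n", x$id, x$genome,
              x$span[1], x$span[2], x$strand,
              paste(x$hits$domain, collapse = ","),
              if (is.null(x$ltr)) "" else sprintf(" LTR %.1f%%", x$ltr$identity)))
  invisible(x)
}

# drop lower-scoring hits overlapping a kept same-profile, same-strand hit
resolve_profile_overlaps <- function(hits) {
  keep <- logical(nrow(hits))
  for (grp in split(seq_len(nrow(hits)),
                    paste(hits$genome, hits$domain, hits$strand))) {
    ord <- grp[order(-hits$score[grp], hits$start[grp])]
    kept <- integer(0)
    for (i in ord) {
      ok <- TRUE
      for (j in kept) {
        if (interval_overlap(hits$start[i], hits$end[i],
                             hits$start[j], hits$end[j]) > 0) { ok <- FALSE; break }
      }
      if (ok) { kept <- c(kept, i); keep[i] <- TRUE }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Chain domain hits into candidate elements
#'
#' Single-linkage chaining of same-strand hits whose genomic gaps are at most
#' `max_gap`; within a chain hits are ordered element 5' to 3' (reverse of the
#' genomic order for minus-strand chains). Overlapping same-profile hits are
#' resolved to the higher score first.
#'
#' @param hits data.frame of domain hits (columns `domain`, `genome`,
#'   `strand`, `start`, `end`, `frame`, `score`, `aaseq`).
#' @param max_gap maximum genomic gap in bp joining two hits.
#' @return list of `element_chain` objects (ORF indices unset).
#' @export
chain_hits <- function(hits, max_gap = 10000) {
  if (nrow(hits) == 0) return(list())
  if (length(unique(hits$genome)) > 1)
    stop_parameter("chain_hits expects hits from a single genome")
  hits <- resolve_profile_overlaps(hits)
  chains <- list()
  for (st in unique(hits$strand)) {
    h <- hits[hits$strand == st, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    brk <- which(h$start[-1] - h$end[-nrow(h)] > max_gap)
    grp <- cumsum(c(1, seq_len(nrow(h) - 1) %in% brk))
    for (g in split(seq_len(nrow(h)), grp)) {
      hh <- h[g, , drop = FALSE]
      if (st == "-") hh <- hh[rev(seq_len(nrow(hh))), , drop = FALSE]
      hh$orf <- NA_integer_
      rownames(hh) <- NULL
      chains[[length(chains) + 1L]] <-
        new_element_chain(NA_character_, hh$genome[1], st, hh)
    }
  }
  ord <- order(vapply(chains, function(c) c$span[1], numeric(1)))
  chains <- chains[ord]
  for (i in seq_along(chains))
    chains[[i]]$id <- sprintf("%s_c%02d", chains[[i]]$genome, i)
  chains
}

dna_submat <- function() {
  if (is.null(.rtt_cache$dnamat))
    .rtt_cache$dnamat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE)
  .rtt_cache$dnamat
}

#' Detect the LTR pair flanking a chain
#'
#' Finds the best repeat shared by the upstream and downstream flanks of the
#' chain span as the optimal local alignment under match +1, mismatch -1,
#' linear gap -2; the pair is reported when the aligned length is at least
#' `min_len` and identity (matches / aligned columns x 100) is at least
#' `min_identity`. Chains closer than `flank` to a contig edge are flagged
#' edge-truncated and get no LTR call (this feeds the lineage filter's
#' third criterion).
#'
#' @param genome a [genome_record()].
#' @param chain an `element_chain`.
#' @param flank bp examined on each side of the chain span.
#' @param min_len minimum aligned LTR length in bp.
#' @param min_identity minimum percent identity.
#' @return list with `found`, `edge_truncated`, and when found `spans`
#'   (0-based half-open genomic intervals `up`/`down`), `identity`, `length`.
#' @export
find_ltrs <- function(genome, chain, flank = 5000, min_len = 100,
                      min_identity = 80) {
  if (flank < min_len) stop_parameter("flank must be >= min_len")
  s <- chain$span[1]; e <- chain$span[2]
  n <- nchar(genome$seq)
  if (s < flank || n - e < flank)
    return(list(found = FALSE, edge_truncated = TRUE))
  up <- substr(genome$seq, s - flank + 1, s)
  down <- substr(genome$seq, e + 1, e + flank)
  aln <- Biostrings::pairwiseAlignment(
    up, down, type = "local", substitutionMatrix = dna_submat(),
    gapOpening = 0, gapExtension = 2)
  pu <- Biostrings::pattern(aln)
  pd <- Biostrings::subject(aln)
  va <- chars(as.character(pu))
  vb <- chars(as.character(pd))
  # the optimal local path can pick up short chance extensions into the
  # unrelated flank beyond the repeat; trim terminal segments below ~75%
  # identity (maximal-scoring subsegment at match +1, mismatch/gap -3)
  colsc <- ifelse(va == vb & va != "-", 1, -3)
  best <- 0; run <- 0; bi <- 0; bj <- -1; start <- 1
  for (k in seq_along(colsc)) {
    if (run <= 0) { run <- colsc[k]; start <- k } else run <- run + colsc[k]
    if (run > best) { best <- run; bi <- start; bj <- k }
  }
  if (bj < bi) return(list(found = FALSE, edge_truncated = FALSE))
  keep <- bi:bj
  alen <- length(keep)
  ident <- 100 * sum(va[keep] == vb[keep] & va[keep] != "-") / alen
  if (alen < min_len || ident < min_identity)
    return(list(found = FALSE, edge_truncated = FALSE))
  pre_a <- if (bi > 1) sum(va[1:(bi - 1)] != "-") else 0L
  suf_a <- if (bj < length(va)) sum(va[(bj + 1):length(va)] != "-") else 0L
  pre_b <- if (bi > 1) sum(vb[1:(bi - 1)] != "-") else 0L
  suf_b <- if (bj < length(vb)) sum(vb[(bj + 1):length(vb)] != "-") else 0L
  list(found = TRUE, edge_truncated = FALSE,
       spans = list(
         up = c(s - flank + IRanges::start(pu) - 1L + pre_a,
                s - flank + IRanges::end(pu) - suf_a),
         down = c(e + IRanges::start(pd) - 1L + pre_b,
                  e + IRanges::end(pd) - suf_b)),
       identity = unname(ident), length = alen)
}

#' Completeness score of a chain
#'
#' `0.8 * (distinct core domains among GAG, PR, RT, RH, INT) / 5 +
#'  0.2 * [LTR pair present]`. Used to pick cluster representatives.
#'
#' @param chain an `element_chain`.
#' @return numeric score in `[0, 1]`.
#' @export
completeness_score <- function(chain) {
  core <- c("GAG", "PR", "RT", "RH", "INT")
  found <- length(intersect(core, unique(chain$hits$domain)))
  has_ltr <- !is.null(chain$ltr) && isTRUE(chain$ltr$found)
  0.8 * found / 5 + 0.2 * as.numeric(has_ltr)
}

#' Mine a genome for LTR retrotransposon elements
#'
#' Six-frame translation, per-profile PSSM scanning at `min_bits` (default
#' 0.4 x the profile self-score), hit chaining, LTR detection and completeness
#' scoring.
#'
#' @param genome a [genome_record()].
#' @param profiles named list of `domain_profile`s.
#' @param min_bits named numeric vector of thresholds per profile, a single
#'   number, or `NULL` for the default.
#' @param max_gap chaining gap in bp.
#' @param flank,ltr_min_len,ltr_min_identity passed to [find_ltrs()].
#' @return list with `hits` (data.frame) and `chains` (list of
#'   `element_chain`s with `ltr` and `completeness` set).
#' @export
mine_genome <- function(genome, profiles, min_bits = NULL, max_gap = 10000,
                        flank = 5000, ltr_min_len = 100,
                        ltr_min_identity = 80) {
  thr <- vapply(profiles, profile_self_score, numeric(1)) * 0.4
  if (!is.null(min_bits)) {
    if (is.null(names(min_bits))) thr[] <- min_bits
    else thr[names(min_bits)] <- min_bits
  }
  frames <- six_frame_translate(genome$seq)
  n <- nchar(genome$seq)
  rows <- list()
  for (fr in frames) {
    for (nm in names(profiles)) {
      hits <- scan_profile(fr$aa, profiles[[nm]], thr[[nm]])
      if (nrow(hits) == 0) next
      L <- nrow(profiles[[nm]]$matrix)
      for (r in seq_len(nrow(hits))) {
        sp <- frame_span(fr$frame, hits$offset[r], L, n)
        rows[[length(rows) + 1L]] <- data.frame(
          domain = nm, genome = genome$id,
          strand = if (fr$frame > 0) "+" else "-",
          start = sp[1], end = sp[2], frame = fr$frame,
          score = hits$score[r],
          aaseq = substr(fr$aa, hits$offset[r] + 1,
                         hits$offset[r] + L),
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows)
          else data.frame(domain = character(0), genome = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0), frame = integer(0),
                          score = numeric(0), aaseq = character(0),
                          stringsAsFactors = FALSE)
  chains <- chain_hits(hits, max_gap = max_gap)
  for (i in seq_along(chains)) {
    lt <- find_ltrs(genome, chains[[i]], flank = flank,
                    min_len = ltr_min_len, min_identity = ltr_min_identity)
    chains[[i]]$edge_truncated <- lt$edge_truncated
    chains[[i]]$ltr <- if (lt$found) lt else NULL
    chains[[i]]$completeness <- completeness_score(chains[[i]])
  }
  list(hits = hits, chains = chains)
}

chain_rt_seq <- function(chain) {
  rt <- chain$hits[chain$hits$domain == "RT", , drop = FALSE]
  if (nrow(rt) == 0) return(NA_character_)
  rt$aaseq[which.max(rt$score)]
}

#' Precluster chains by RT amino-acid identity
#'
#' Single-linkage clustering on pairwise RT identity (global alignment); the
#' representative of each cluster has the highest completeness score, ties
#' broken by longer chain span, then lexicographic id. Chains lacking RT are
#' passed through as flagged singletons.
#'
#' @param chains list of `element_chain`s.
#' @param identity_threshold linking threshold, percent.
#' @return list of clusters, each `list(members, representative, has_rt)`.
#' @export
precluster_by_rt <- function(chains, identity_threshold = 80) {
  ids <- vapply(chains, `[[`, character(1), "id")
  names(chains) <- ids
  rts <- vapply(chains, chain_rt_seq, character(1))
  no_rt <- ids[is.na(rts)]
  with_rt <- ids[!is.na(rts)]
  clusters <- lapply(no_rt, function(id)
    list(members = id, representative = id, has_rt = FALSE))
  if (length(with_rt) > 0) {
    k <- length(with_rt)
    parent <- seq_len(k)
    findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (k > 1) {
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        al <- align_pair(rts[[with_rt[i]]], rts[[with_rt[j]]])
        if (pairwise_identity(al[1], al[2]) >= identity_threshold) {
          pi <- findp(i); pj <- findp(j)
          if (pi != pj) parent[pj] <- pi
        }
      }
    }
    comp <- vapply(seq_len(k), findp, integer(1))
    for (g in split(with_rt, comp)) {
      members <- sort(g)
      cs <- vapply(chains[members], function(c) {
        if (is.na(c$completeness)) completeness_score(c) else c$completeness
      }, numeric(1))
      spans <- vapply(chains[members], function(c) diff(c$span), numeric(1))
      ord <- order(-cs, -spans, members)
      clusters[[length(clusters) + 1L]] <-
        list(members = members, representative = members[ord[1]],
             has_rt = TRUE)
    }
  }
  clusters
}
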