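# PSSM construction and six-frame profile scanning.
#
# Stands in for RPS-BLAST profile searches at desk scale: per-position
# log-odds matrices in bits, scanned gaplessly over six-frame translations.

#' Build a position-specific scoring matrix from an alignment
#'
#' Per column `i` and residue `a`:
#' `score[i, a] = log2((count_i(a) + pseudocount * background[a]) /
#'                     (total_i + pseudocount) / background[a])`.
#' Gap characters (`-`, `.`) are excluded from counts.
#'
#' @param alignment character vector of equal-length aligned amino-acid rows.
#' @param name profile name.
#' @param pseudocount pseudocount weight (total extra observations spread
#'   according to the background).
#' @param background named residue frequency vector over the 20 amino acids;
#'   defaults to uniform (1/20).
#' @param catalytic_positions optional data.frame (`pos`, `res`) of catalytic
#'   core positions, carried for RH-type profiles.
#' @return an object of class `domain_profile` with fields `name`, `matrix`
#'   (L x 20, bits), `background`, `consensus`, `catalytic_positions`.
#' @export
build_pssm <- function(alignment, name = "profile", pseudocount = 1,
                       background = NULL, catalytic_positions = NULL) {
  if (length(alignment) < 1) stop_format("alignment needs at least one row")
  L <- nchar(alignment[1])
  if (any(nchar(alignment) != L)) stop_format("ragged alignment")
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  background <- background[AA20]
  rows <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  mat <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  consensus <- character(L)
  for (i in seq_len(L)) {
    col <- rows[, i]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    tot <- sum(cnt)
    denom <- tot + pseudocount
    if (denom > 0) {
      mat[i, ] <- log2((as.numeric(cnt) + pseudocount * background) /
                         denom / background)
    }
    consensus[i] <- if (tot > 0) AA20[which.max(cnt)] else "X"
  }
  structure(list(name = name, matrix = mat, background = background,
                 consensus = paste(consensus, collapse = ""),
                 catalytic_positions = catalytic_positions),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile %s, %d columns, self-score %.1f bits>\n",
              x$name, nrow(x$matrix), profile_self_score(x)))
  invisible(x)
}

#' Self-score of a profile
#'
#' Score of the profile consensus against its own matrix; the default
#' calling threshold is a fraction of this value.
#'
#' @param profile a `domain_profile`.
#' @return numeric score in bits.
#' @export
profile_self_score <- function(profile) {
  cons <- chars(profile$consensus)
  sum(profile$matrix[cbind(seq_along(cons), match(cons, AA20))])
}

#' Six-frame translation
#'
#' Translates frames +1, +2, +3 and (on the reverse complement) -1, -2, -3
#' under the standard genetic code; codons containing `N` give `X`, stops
#' give `*`.
#'
#' @param dna DNA string over `ACGTN`.
#' @return list of six records, each with `frame` and `aa`.
#' @export
six_frame_translate <- function(dna) {
  n <- nchar(dna)
  rc <- revcomp(dna)
  out <- list()
  for (f in 1:3) {
    out[[length(out) + 1L]] <-
      list(frame = f, aa = translate_dna(substr(dna, f, n)))
    out[[length(out) + 1L]] <-
      list(frame = -f, aa = translate_dna(substr(rc, f, n)))
  }
  out
}

# Genomic 0-based half-open span of a gapless hit: frame f, amino-acid offset
# `off` (0-based) and length `L_aa`, genome length n.
frame_span <- function(frame, off, L_aa, n) {
  w <- 3L * L_aa
  if (frame > 0) {
    s <- (frame - 1L) + 3L * off
    c(s, s + w)
  } else {
    rs <- (-frame - 1L) + 3L * off
    c(n - rs - w, n - rs)
  }
}

#' Scan a translated frame with a profile
#'
#' Gapless sliding-window scoring: `score(offset) = sum_i matrix[i, aa[offset + i]]`.
#' Windows containing a stop (`*`) or any non-standard residue are discarded.
#' Returns maximal-scoring non-overlapping offsets with score `>= min_bits`,
#' chosen greedily by score.
#'
#' @param aa amino-acid string.
#' @param profile a `domain_profile`.
#' @param min_bits score threshold in bits.
#' @return data.frame with columns `offset` (0-based) and `score`.
#' @export
scan_profile <- function(aa, profile, min_bits) {
  L <- nrow(profile$matrix)
  n <- nchar(aa)
  empty <- data.frame(offset = integer(0), score = numeric(0))
  if (n < L) return(empty)
  v <- chars(aa)
  code <- match(v, AA20)
  bad <- as.integer(is.na(code))
  code[is.na(code)] <- 1L
  nw <- n - L + 1L
  cb <- cumsum(c(0L, bad))
  badw <- (cb[(1:nw) + L] - cb[1:nw]) > 0
  sc <- numeric(nw)
  for (i in seq_len(L)) {
    mi <- profile$matrix[i, ]
    sc <- sc + mi[code[i:(i + nw - 1L)]]
  }
  sc[badw] <- -Inf
  cand <- which(sc >= min_bits)
  if (length(cand) == 0) return(empty)
  cand <- cand[order(-sc[cand], cand)]
  taken <- logical(n)
  keep <- integer(0)
  for (o in cand) {
    if (!any(taken[o:(o + L - 1L)])) {
      keep <- c(keep, o)
      taken[o:(o + L - 1L)] <- TRUE
    }
  }
  keep <- sort(keep)
  data.frame(offset = keep - 1L, score = unname(sc[keep]))
}

#' Build scannable profiles from a domain-spec library
#'
#' Emulates profile construction from curated multiple alignments: each
#' domain's alignment is its consensus plus `n_seqs - 1` mutated copies
#' (catalytic positions frozen), turned into a PSSM.
#'
#' @param library [make_profile_library()] output.
#' @param n_seqs rows per alignment.
#' @param divergence substitution proportion of the mutated rows.
#' @param pseudocount passed to [build_pssm()].
#' @param seed integer seed.
#' @return named list of `domain_profile`s (and the underlying alignments as
#'   attribute `"alignments"`).
#' @export
profiles_from_specs <- function(library, n_seqs = 8, divergence = 0.1,
                                pseudocount = 1, seed = 1L) {
  alns <- with_seed(seed, {
    lapply(library, function(spec) {
      frozen <- if (!is.null(spec$catalytic_positions))
        spec$catalytic_positions$pos else integer(0)
      c(spec$consensus,
        vapply(seq_len(n_seqs - 1), function(i)
          .mutate_protein(spec$consensus, divergence, frozen), character(1)))
    })
  })
  profs <- lapply(names(library), function(nm)
    build_pssm(alns[[nm]], name = nm, pseudocount = pseudocount,
               catalytic_positions = library[[nm]]$catalytic_positions))
  names(profs) <- names(library)
  attr(profs, "alignments") <- alns
  profs
}

#' Write a profile library to a directory
#'
#' One aligned FASTA per domain plus `catalytic.tsv` (columns `domain`,
#' `pos`, `res`) annotating RH-type catalytic cores.
#'
#' @param profiles output of [profiles_from_specs()] (alignments attached) or
#'   a named list of alignments.
#' @param dir output directory, created if needed.
#' @export
write_profile_library <- function(profiles, dir) {
  alns <- attr(profiles, "alignments")
  if (is.null(alns)) stop_parameter("profiles carry no alignments to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat_rows <- list()
  for (nm in names(alns)) {
    ss <- Biostrings::AAStringSet(alns[[nm]])
    names(ss) <- sprintf("%s_%02d", nm, seq_along(alns[[nm]]))
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(nm, ".fasta")))
    cp <- profiles[[nm]]$catalytic_positions
    if (!is.null(cp))
      cat_rows[[nm]] <- data.frame(domain = nm, pos = cp$pos, res = cp$res)
  }
  ct <- if (length(cat_rows)) do.call(rbind, cat_rows)
        else data.frame(domain = character(0), pos = integer(0),
                        res = character(0))
  utils::write.table(ct, file.path(dir, "catalytic.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a profile library from a directory
#'
#' @param dir directory written by [write_profile_library()] (or any set of
#'   `<DOMAIN>.fasta` alignments plus optional `catalytic.tsv`).
#' @param pseudocount passed to [build_pssm()].
#' @return named list of `domain_profile`s.
#' @export
read_profile_library <- function(dir, pseudocount = 1) {
  files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  if (length(files) == 0) stop_format("no .fasta alignments found")
  cat_path <- file.path(dir, "catalytic.tsv")
  ct <- if (file.exists(cat_path))
    utils::read.table(cat_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else data.frame(domain = character(0), pos = integer(0), res = character(0))
  profs <- list()
  alns <- list()
  for (f in files) {
    nm <- sub("\\.fasta$", "", basename(f))
    rows <- as.character(Biostrings::readAAStringSet(f))
    cp <- ct[ct$domain == nm, c("pos", "res")]
    if (nrow(cp) == 0) cp <- NULL
    profs[[nm]] <- build_pssm(unname(rows), name = nm,
                              pseudocount = pseudocount,
                              catalytic_positions = cp)
    alns[[nm]] <- unname(rows)
  }
  attr(profs, "alignments") <- alns
  profs
}
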