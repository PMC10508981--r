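# Needleman-Wunsch machinery shared by profile alignment, pairwise protein
# alignment and progressive profile merging. Linear gap penalties throughout
# (short domains; keeps the oracle simple).

# Global alignment over a precomputed position score matrix S (L x M):
# row i of S scores pairing item i of A with item j of B. Linear gap `gap`.
# Returns the optimal score and the aligned index pairs (NA = gap), using a
# row-vectorized recurrence (the within-row gap chain is folded into a
# running cummax) and value-based traceback preferring diagonal, then up.
nw_core <- function(S, gap) {
  L <- nrow(S); M <- ncol(S)
  H <- matrix(0, L + 1, M + 1)
  H[1, ] <- gap * (0:M)
  H[, 1] <- gap * (0:L)
  jj <- seq_len(M)
  for (i in seq_len(L)) {
    b <- pmax(H[i, jj] + S[i, ], H[i, jj + 1] + gap)
    z <- pmax(cummax(b - gap * jj), H[i + 1, 1])
    H[i + 1, jj + 1] <- z + gap * jj
  }
  eps <- 1e-9
  ai <- integer(0); bj <- integer(0)
  i <- L; j <- M
  while (i > 0 || j > 0) {
    h <- H[i + 1, j + 1]
    if (i > 0 && j > 0 && H[i, j] + S[i, j] >= h - eps) {
      ai <- c(i, ai); bj <- c(j, bj); i <- i - 1; j <- j - 1
    } else if (i > 0 && H[i, j + 1] + gap >= h - eps) {
      ai <- c(i, ai); bj <- c(NA_integer_, bj); i <- i - 1
    } else {
      ai <- c(NA_integer_, ai); bj <- c(j, bj); j <- j - 1
    }
  }
  list(score = H[L + 1, M + 1], ai = ai, bj = bj)
}

blosum62 <- function() {
  if (is.null(.rtt_cache$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .rtt_cache$blosum <- e$BLOSUM62[AA20, AA20]
  }
  .rtt_cache$blosum
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch with BLOSUM62 substitution scores and a linear gap
#' penalty; used for RT preclustering identities.
#'
#' @param a,b amino-acid strings.
#' @param gap linear gap penalty (negative).
#' @return character vector of the two aligned (gapped) rows, with the
#'   alignment score as attribute `"score"`.
#' @export
align_pair <- function(a, b, gap = -4) {
  if (nchar(a) == 0 || nchar(b) == 0)
    stop_parameter("cannot align an empty sequence")
  va <- chars(a); vb <- chars(b)
  bm <- blosum62()
  ia <- match(va, AA20); ib <- match(vb, AA20)
  S <- matrix(0, length(va), length(vb))
  ok <- !is.na(ia)
  okb <- !is.na(ib)
  S[ok, okb] <- bm[ia[ok], ib[okb], drop = FALSE]
  r <- nw_core(S, gap)
  out <- c(paste(ifelse(is.na(r$ai), "-", va[r$ai]), collapse = ""),
           paste(ifelse(is.na(r$bj), "-", vb[r$bj]), collapse = ""))
  attr(out, "score") <- r$score
  out
}
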