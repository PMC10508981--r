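# Tether-like degradation of the RNase H catalytic core.
#
# A candidate RH-type domain is aligned to its reference profile, the
# residues sitting at the four DEDD catalytic positions are read out, and a
# domain is called degraded when at least `degraded_threshold` canonical
# carboxylates are lost. Matching is exact (no D/E credit): a conservative
# swap still reads as a loss but remains visible in `core_state`.

#' Align a sequence to a profile
#'
#' Global alignment of a sequence against a profile's consensus, scoring each
#' pairing from the profile's per-position log-odds columns with a linear gap
#' penalty, returning the consensus-position to sequence-position map.
#'
#' The default penalty is -6 bits: at -4, a chance background substitution
#' that creates a D/E next to a degraded catalytic position can pay for a
#' gap-pair shift that "rescues" the core readout (~1% of diverged domains);
#' -6 makes the shift unprofitable while leaving genuine indel placement
#' unchanged.
#'
#' @param seq amino-acid string.
#' @param profile a `domain_profile`.
#' @param gap linear gap penalty in bits.
#' @return list with `score`, `map` (integer vector over consensus positions;
#'   1-based index into `seq`, `NA` where the consensus position is deleted),
#'   and the two `aligned` rows.
#' @export
align_to_profile <- function(seq, profile, gap = -6) {
  if (!nzchar(seq)) stop_parameter("empty sequence")
  v <- chars(seq)
  L <- nrow(profile$matrix)
  code <- match(v, AA20)
  S <- matrix(0, L, length(v))
  ok <- which(!is.na(code))
  if (length(ok)) S[, ok] <- profile$matrix[, code[ok], drop = FALSE]
  r <- nw_core(S, gap)
  map <- rep(NA_integer_, L)
  both <- !is.na(r$ai) & !is.na(r$bj)
  map[r$ai[both]] <- as.integer(r$bj[both])
  cons <- chars(profile$consensus)
  list(score = r$score, map = map,
       aligned = c(paste(ifelse(is.na(r$ai), "-", cons[r$ai]), collapse = ""),
                   paste(ifelse(is.na(r$bj), "-", v[r$bj]), collapse = "")))
}

#' Read the catalytic core state of an RH-type domain
#'
#' @param seq amino-acid string of the candidate domain.
#' @param profile a `domain_profile` with four annotated catalytic positions.
#' @param degraded_threshold minimum number of lost canonical residues that
#'   calls the domain degraded (default 1: a single DEDD substitution
#'   abolishes catalysis).
#' @return an object of class `rh_assessment`: `core_state` (4 characters,
#'   `-` where the position is gapped), `intact_count`, `severity`
#'   (`4 - intact_count`), `degraded`.
#' @export
catalytic_core_state <- function(seq, profile, degraded_threshold = 1) {
  cp <- profile$catalytic_positions
  if (is.null(cp) || nrow(cp) != 4)
    stop_parameter("profile lacks the four catalytic position annotations")
  al <- align_to_profile(seq, profile)
  v <- chars(seq)
  res <- vapply(cp$pos, function(p) {
    j <- al$map[p]
    if (is.na(j)) "-" else v[j]
  }, character(1))
  intact <- sum(res == cp$res)
  sev <- 4L - intact
  structure(list(core_state = paste(res, collapse = ""),
                 intact_count = intact, severity = sev,
                 degraded = sev >= degraded_threshold,
                 alignment_score = al$score),
            class = "rh_assessment")
}

#' @export
print.rh_assessment <- function(x, ...) {
  cat(sprintf("<rh_assessment core %s, severity %d%s>\n", x$core_state,
              x$severity, if (x$degraded) " (degraded)" else ""))
  invisible(x)
}

#' Assess all RH-type domains of a chain
#'
#' Native RH hits get role `native_RH`; aRH hits get `aRH_proximal` (the
#' first, or only, aRH in element order) or `aRH_distal` (the second).
#'
#' @param chain an `element_chain`.
#' @param profiles named list of `domain_profile`s (needs `RH` and `ARH`).
#' @param degraded_threshold see [catalytic_core_state()].
#' @return data.frame with one row per RH-type hit: `element_id`, `genome`,
#'   `domain`, `role`, `core_state`, `intact_count`, `severity`, `degraded`.
#' @export
assess_chain_rh <- function(chain, profiles, degraded_threshold = 1) {
  h <- chain$hits
  rows <- list()
  arh_seen <- 0L
  for (i in seq_len(nrow(h))) {
    dom <- h$domain[i]
    if (!dom %in% c("RH", "ARH")) next
    role <- if (dom == "RH") "native_RH" else {
      arh_seen <- arh_seen + 1L
      if (arh_seen == 1L) "aRH_proximal" else "aRH_distal"
    }
    a <- catalytic_core_state(h$aaseq[i], profiles[[dom]],
                              degraded_threshold = degraded_threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = chain$id, genome = chain$genome, domain = dom, role = role,
      core_state = a$core_state, intact_count = a$intact_count,
      severity = a$severity, degraded = a$degraded, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(element_id = character(0), genome = character(0),
                      domain = character(0), role = character(0),
                      core_state = character(0), intact_count = integer(0),
                      severity = integer(0), degraded = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summarize degradation per structure and domain role
#'
#' @param assessments data.frame with columns `structure`, `role`,
#'   `severity`, `degraded` (one row per assessed domain; join structure
#'   labels onto [assess_chain_rh()] output first).
#' @return data.frame with `structure`, `role`, `n`, `mean_severity`,
#'   `fraction_degraded`; empty groups are omitted.
#' @export
degradation_report <- function(assessments) {
  if (nrow(assessments) == 0)
    return(data.frame(structure = character(0), role = character(0),
                      n = integer(0), mean_severity = numeric(0),
                      fraction_degraded = numeric(0), stringsAsFactors = FALSE))
  key <- interaction(assessments$structure, assessments$role, drop = TRUE)
  out <- do.call(rbind, lapply(split(assessments, key), function(g)
    data.frame(structure = g$structure[1], role = g$role[1], n = nrow(g),
               mean_severity = mean(g$severity),
               fraction_degraded = mean(g$degraded),
               stringsAsFactors = FALSE)))
  out <- out[order(out$structure, out$role), , drop = FALSE]
  rownames(out) <- NULL
  out
}
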