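# Synthetic genomes with planted LTR retrotransposons.
#
# The generator emits the stated world the rest of the pipeline is tested
# against: elements with paired LTRs of configurable divergence, gag/pol ORFs
# encoding domain chains in canonical order, the five placements of the
# additional archaeal-type RNase H (aRH) domain plus aRH-less elements, and
# intact or degraded DEDD catalytic cores, embedded in i.i.d. intergenic
# background. Ground truth is machine-readable so recovery is checkable.

#' Domain specification
#'
#' A named protein domain with a consensus sequence and, for RNase H-type
#' domains, the four catalytic core positions (canonically D, E, D, D).
#'
#' @param name one of `"GAG"`, `"PR"`, `"RT"`, `"RH"`, `"ARH"`, `"INT"`.
#' @param consensus amino-acid string.
#' @param catalytic_positions `NULL`, or a data.frame with columns `pos`
#'   (1-based index into the consensus) and `res` (canonical residue, D or E).
#' @return an object of class `domain_spec`.
#' @export
domain_spec <- function(name, consensus, catalytic_positions = NULL) {
  if (!is.null(catalytic_positions)) {
    if (any(catalytic_positions$pos > nchar(consensus)))
      stop_parameter("catalytic position beyond consensus length")
    if (!all(catalytic_positions$res %in% c("D", "E")))
      stop_parameter("catalytic residues must be D or E")
  }
  structure(list(name = name, length = nchar(consensus),
                 consensus = consensus,
                 catalytic_positions = catalytic_positions),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf("<domain_spec %s, %d aa%s>\n", x$name, x$length,
              if (is.null(x$catalytic_positions)) ""
              else paste0(", core ",
                          paste(x$catalytic_positions$res, collapse = ""))))
  invisible(x)
}

# Catalytic core layout used for generated RH-type domains: positions are
# spread across the domain the way the DEDD carboxylates sit in the RNase H
# fold (first D early, E mid, D-D toward the C-terminus).
core_positions <- function(len) {
  data.frame(pos = pmax(1, round(len * c(0.08, 0.37, 0.69, 0.91))),
             res = c("D", "E", "D", "D"))
}

#' Generate the six-domain profile library
#'
#' Produces seed-deterministic consensus sequences for GAG, PR, RT, RH, ARH
#' and INT. The native RH and the aRH consensus share the DEDD catalytic core
#' but are otherwise independent draws (pairwise identity well below 60%), so
#' PSSM scanning can separate the two domain types. Default lengths:
#' GAG 80, PR 100, RT 200, RH 130, ARH 130 (the aRH domain is ~130 aa),
#' INT 150.
#'
#' @param seed integer seed.
#' @param lengths named integer vector of domain lengths.
#' @return named list of [domain_spec()] objects.
#' @export
make_profile_library <- function(seed,
                                 lengths = c(GAG = 80, PR = 100, RT = 200,
                                             RH = 130, ARH = 130, INT = 150)) {
  needed <- c("GAG", "PR", "RT", "RH", "ARH", "INT")
  if (!all(needed %in% names(lengths)))
    stop_parameter("lengths must name all six domains")
  with_seed(seed, {
    lib <- list()
    for (nm in needed) {
      len <- as.integer(lengths[[nm]])
      cp <- if (nm %in% c("RH", "ARH")) core_positions(len) else NULL
      repeat {
        cons <- chars(random_aa(len))
        if (!is.null(cp)) cons[cp$pos] <- cp$res
        cons <- paste(cons, collapse = "")
        if (nm != "ARH") break
        # guarantee RH/ARH separability regardless of seed
        same <- mean(chars(cons) == chars(lib$RH$consensus))
        if (same < 0.6) break
      }
      lib[[nm]] <- domain_spec(nm, cons, cp)
    }
    lib
  })
}

.mutate_protein <- function(s, rate, frozen = integer(0)) {
  v <- chars(s)
  hit <- which(stats::runif(length(v)) < rate)
  hit <- setdiff(hit, frozen)
  for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1)
  paste(v, collapse = "")
}

#' Mutate a protein sequence
#'
#' Each non-frozen position is independently substituted with probability
#' `rate` to a uniformly chosen different residue.
#'
#' @param seq amino-acid string.
#' @param rate substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @param frozen integer vector of 1-based positions left untouched.
#' @return mutated amino-acid string of the same length.
#' @export
mutate_protein <- function(seq, rate, seed, frozen = integer(0)) {
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stop_parameter("rate must be in [0, 1]")
  if (length(frozen) && (any(frozen < 1) || any(frozen > nchar(seq))))
    stop_parameter("frozen positions out of range")
  with_seed(seed, .mutate_protein(seq, rate, frozen))
}

# synonymous codon table, stops excluded
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}
.rtt_cache <- new.env(parent = emptyenv())
codons_for <- function() {
  if (is.null(.rtt_cache$codons)) .rtt_cache$codons <- codon_table()
  .rtt_cache$codons
}

.back_translate <- function(seq) {
  tab <- codons_for()
  v <- chars(seq)
  paste(vapply(v, function(a) {
    cs <- tab[[a]]
    if (length(cs) == 1) cs else sample(cs, 1)
  }, character(1)), collapse = "")
}

#' Back-translate a protein to DNA
#'
#' Codons are chosen uniformly among synonymous codons (seed-deterministic);
#' translating the result under the standard genetic code returns the input.
#'
#' @param seq amino-acid string (standard residues only).
#' @param seed integer seed.
#' @return DNA string of length `3 * nchar(seq)`.
#' @export
back_translate <- function(seq, seed) {
  if (!all(chars(seq) %in% AA20))
    stop_parameter("non-standard amino acid in sequence")
  with_seed(seed, .back_translate(seq))
}

.mutate_dna <- function(s, rate) {
  v <- chars(s)
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(DNA4, v[i]), 1)
  paste(v, collapse = "")
}

.degrade_core <- function(s, positions) {
  v <- chars(s)
  v[positions] <- sample(DEGRADED_RESIDUES, length(positions), replace = TRUE)
  paste(v, collapse = "")
}

# background / spacer DNA free of ATG so no spurious ORF starts are planted
.spacer_dna <- function(n, gc = 0.5) {
  s <- random_dna(n, gc)
  while (grepl("ATG", s, fixed = TRUE)) s <- gsub("ATG", "ACG", s, fixed = TRUE)
  s
}

#' Element blueprint
#'
#' Declares one element to plant: its structural variant, LTR geometry and
#' divergence, domain divergence from consensus, and catalytic-core state.
#'
#' @param structure one of `"S1".."S5"`, `"NO_ARH"`.
#' @param ltr_length LTR length in bp.
#' @param ltr_divergence substitution proportion between the two LTRs,
#'   in `[0, 0.5]`.
#' @param domain_divergence amino-acid substitution proportion from consensus,
#'   in `[0, 0.5]`.
#' @param degrade_native_rh substitute the four native-RH catalytic residues
#'   to non-carboxylate residues (the tether state).
#' @param degrade_distal_arh degrade the distal aRH core; only valid for S5.
#' @param seed integer seed for this element's construction.
#' @return an object of class `element_blueprint`.
#' @export
element_blueprint <- function(structure, ltr_length = 300,
                              ltr_divergence = 0, domain_divergence = 0,
                              degrade_native_rh = FALSE,
                              degrade_distal_arh = FALSE, seed = 1L) {
  if (!structure %in% c("S1", "S2", "S3", "S4", "S5", "NO_ARH"))
    stop_parameter("unknown structure label")
  if (ltr_divergence < 0 || ltr_divergence > 0.5 ||
      domain_divergence < 0 || domain_divergence > 0.5)
    stop_parameter("divergences must be in [0, 0.5]")
  if (degrade_distal_arh && structure != "S5")
    stop_parameter("degrade_distal_arh is only meaningful for S5")
  structure(list(structure = structure, ltr_length = as.integer(ltr_length),
                 ltr_divergence = ltr_divergence,
                 domain_divergence = domain_divergence,
                 degrade_native_rh = isTRUE(degrade_native_rh),
                 degrade_distal_arh = isTRUE(degrade_distal_arh),
                 seed = as.integer(seed)),
            class = "element_blueprint")
}

# ORF layout per structural variant; list names are ORF roles in element
# order. int_position = "after_pr" emulates the chromoviral PR-INT-RT-RH
# arrangement instead of the default INT-last convention.
structure_orf_map <- function(structure, int_position = "last") {
  m <- switch(structure,
    S1     = list(gag = "GAG", pol = c("PR", "RT", "RH", "ARH", "INT")),
    S2     = list(gag = "GAG", pol = c("PR", "ARH", "RT", "RH", "INT")),
    S3     = list(gag = "GAG", arh = "ARH", pol = c("PR", "RT", "RH", "INT")),
    S4     = list(arh = "ARH", gag = "GAG", pol = c("PR", "RT", "RH", "INT")),
    S5     = list(gag = "GAG", pol = c("PR", "RT", "RH", "ARH", "ARH", "INT")),
    NO_ARH = list(gag = "GAG", pol = c("PR", "RT", "RH", "INT")),
    stop_parameter("unknown structure label"))
  if (int_position == "after_pr") {
    pol <- setdiff(m$pol, "INT")
    at <- which(pol == "PR")
    m$pol <- append(pol, "INT", after = at)
  }
  m
}

#' Build one LTR retrotransposon element
#'
#' Emits `5'LTR + coding region + 3'LTR` on the plus strand, with ORFs
#' (`ATG ... stop`, no internal in-frame stops) encoding the domain chain of
#' the requested structural variant, and returns the element-local ground
#' truth (all coordinates 0-based half-open).
#'
#' @param blueprint an [element_blueprint()].
#' @param library the [make_profile_library()] output.
#' @param seed integer seed; defaults to the blueprint's own seed.
#' @param int_position `"last"` (canonical Ty3/gypsy pol order PR-RT-RH-INT)
#'   or `"after_pr"` (chromoviral placement).
#' @return list with `dna` (string) and `truth` (element-local truth record:
#'   `ltr_spans`, `domain_spans`, `orf_spans`, `rh_core_state`,
#'   `arh_core_states`, `structure`).
#' @export
build_element <- function(blueprint, library, seed = blueprint$seed,
                          int_position = "last") {
  needed <- c("GAG", "PR", "RT", "RH", "ARH", "INT")
  if (!all(needed %in% names(library)))
    stop_parameter("library must contain all six domains")
  bp <- blueprint
  with_seed(seed, {
    ltr5 <- random_dna(bp$ltr_length, 0.5)
    ltr3 <- .mutate_dna(ltr5, bp$ltr_divergence)

    orf_map <- structure_orf_map(bp$structure, int_position)
    n_arh_seen <- 0L
    rh_core <- NA_character_
    arh_cores <- character(0)

    pieces <- list(ltr5)
    pos <- nchar(ltr5)
    dom_rows <- list()
    orf_rows <- list()

    for (orf_name in names(orf_map)) {
      spacer <- .spacer_dna(sample(20:200, 1))
      pieces[[length(pieces) + 1L]] <- spacer
      pos <- pos + nchar(spacer)

      prot <- "M"
      dom_aa <- list()  # per-domain aa offsets (0-based within protein)
      for (dom in orf_map[[orf_name]]) {
        spec <- library[[dom]]
        s <- spec$consensus
        role <- ""
        if (dom == "ARH") {
          n_arh_seen <- n_arh_seen + 1L
          role <- if (bp$structure == "S5" && n_arh_seen == 2L) "distal"
                  else "proximal"
          if (role == "distal" && bp$degrade_distal_arh)
            s <- .degrade_core(s, spec$catalytic_positions$pos)
        }
        if (dom == "RH" && bp$degrade_native_rh)
          s <- .degrade_core(s, spec$catalytic_positions$pos)
        frozen <- if (!is.null(spec$catalytic_positions))
          spec$catalytic_positions$pos else integer(0)
        s <- .mutate_protein(s, bp$domain_divergence, frozen)
        if (!is.null(spec$catalytic_positions)) {
          core <- paste(chars(s)[spec$catalytic_positions$pos], collapse = "")
          if (dom == "RH") rh_core <- core
          if (dom == "ARH") arh_cores[role] <- core
        }
        off <- nchar(prot)
        dom_aa[[length(dom_aa) + 1L]] <-
          list(dom = dom, role = role, off = off, len = nchar(s))
        prot <- paste0(prot, s)
        if (dom != utils::tail(orf_map[[orf_name]], 1))
          prot <- paste0(prot, random_aa(sample(4:10, 1)))  # inter-domain linker
      }
      orf_dna <- paste0(.back_translate(prot), "TAA")
      for (d in dom_aa) {
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          domain = d$dom, role = d$role,
          start = pos + 3L * d$off, end = pos + 3L * (d$off + d$len),
          orf = orf_name, stringsAsFactors = FALSE)
      }
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        orf = orf_name, start = pos, end = pos + nchar(orf_dna),
        stringsAsFactors = FALSE)
      pieces[[length(pieces) + 1L]] <- orf_dna
      pos <- pos + nchar(orf_dna)
    }
    spacer <- .spacer_dna(sample(20:200, 1))
    pieces[[length(pieces) + 1L]] <- spacer
    pos <- pos + nchar(spacer)
    pieces[[length(pieces) + 1L]] <- ltr3

    dna <- paste(unlist(pieces), collapse = "")
    truth <- list(
      structure = bp$structure,
      ltr_spans = list(five = c(0L, bp$ltr_length),
                       three = c(pos, pos + bp$ltr_length)),
      domain_spans = do.call(rbind, dom_rows),
      orf_spans = do.call(rbind, orf_rows),
      rh_core_state = rh_core,
      arh_core_states = arh_cores)
    list(dna = dna, truth = truth)
  })
}

#' Genome record
#'
#' @param id sequence identifier.
#' @param seq DNA string.
#' @param taxon optional taxon label carried into reports.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(id, seq, taxon = NA_character_) {
  structure(list(id = id, seq = seq, taxon = taxon), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record %s, %d bp>\n", x$id, nchar(x$seq)))
  invisible(x)
}

# reflect an element-local 0-based half-open span onto forward genome
# coordinates for an element of length `len` inserted at `off` on strand `st`
place_span <- function(span, off, len, st) {
  if (st == "+") c(off + span[1], off + span[2])
  else c(off + len - span[2], off + len - span[1])
}

#' Plant elements into a background genome
#'
#' Elements are placed at non-overlapping, seed-deterministic positions on
#' seed-chosen strands (minus-strand elements are reverse-complemented);
#' the background is i.i.d. nucleotides at the given GC. Placement keeps a
#' contig margin (so LTR flank windows stay on-contig) and a minimum
#' inter-element gap (the generator's world has no nested or abutting
#' insertions); both are configurable.
#'
#' @param genome_length total genome length in bp.
#' @param blueprints list of [element_blueprint()]s.
#' @param library [make_profile_library()] output.
#' @param gc background GC proportion.
#' @param seed integer seed for placement, strands and background.
#' @param genome_id identifier for the emitted genome.
#' @param taxon optional taxon label.
#' @param margin bp of background kept at each contig end.
#' @param min_gap minimum bp of background between consecutive elements.
#' @param int_position passed to [build_element()].
#' @return list with `genome` (a [genome_record()]) and `truth`
#'   (list of per-element ground-truth records, genome coordinates,
#'   0-based half-open).
#' @export
plant_elements <- function(genome_length, blueprints, library, gc = 0.4,
                           seed = 1L, genome_id = "synth1",
                           taxon = NA_character_,
                           margin = 6000L, min_gap = 15000L,
                           int_position = "last") {
  K <- length(blueprints)
  built <- lapply(blueprints, build_element, library = library,
                  int_position = int_position)
  lens <- vapply(built, function(b) nchar(b$dna), integer(1))
  if (K > 0 && sum(lens) > 0.8 * genome_length)
    stop_capacity("planted elements exceed 80% of the genome length")
  if (K == 0) {
    bg <- with_seed(seed, random_dna(genome_length, gc))
    return(list(genome = genome_record(genome_id, bg, taxon), truth = list()))
  }
  with_seed(seed, {
    slack <- genome_length - 2 * margin - sum(lens) - max(0, K - 1) * min_gap
    if (slack < 0)
      stop_capacity("elements cannot be placed without overlap at the requested margins")
    u <- if (K >= 1) sort(stats::runif(K)) else numeric(0)
    extra <- floor(diff(c(0, u, 1)) * slack)
    extra[K + 1] <- extra[K + 1] + (slack - sum(extra))
    gaps <- c(margin + extra[1],
              if (K > 1) min_gap + extra[2:K] else integer(0),
              margin + extra[K + 1])
    strands <- sample(c("+", "-"), K, replace = TRUE)

    pieces <- character(0)
    truths <- list()
    pos <- 0L
    for (i in seq_len(K)) {
      bg <- random_dna(gaps[i], gc)
      pieces <- c(pieces, bg)
      pos <- pos + nchar(bg)
      el <- built[[i]]
      st <- strands[i]
      dna <- if (st == "+") el$dna else revcomp(el$dna)
      off <- pos
      len <- lens[i]
      tr <- el$truth
      ds <- tr$domain_spans
      placed <- t(vapply(seq_len(nrow(ds)), function(r)
        place_span(c(ds$start[r], ds$end[r]), off, len, st), numeric(2)))
      ds$start <- as.integer(placed[, 1]); ds$end <- as.integer(placed[, 2])
      os <- tr$orf_spans
      placed <- t(vapply(seq_len(nrow(os)), function(r)
        place_span(c(os$start[r], os$end[r]), off, len, st), numeric(2)))
      os$start <- as.integer(placed[, 1]); os$end <- as.integer(placed[, 2])
      truths[[i]] <- list(
        element_id = sprintf("%s_e%02d", genome_id, i),
        genome_id = genome_id,
        span = c(off, off + len),
        strand = st,
        structure = tr$structure,
        ltr_spans = list(
          five = as.integer(place_span(tr$ltr_spans$five, off, len, st)),
          three = as.integer(place_span(tr$ltr_spans$three, off, len, st))),
        domain_spans = ds,
        orf_spans = os,
        rh_core_state = tr$rh_core_state,
        arh_core_states = tr$arh_core_states)
      pieces <- c(pieces, dna)
      pos <- pos + len
    }
    pieces <- c(pieces, random_dna(gaps[K + 1], gc))
    genome <- genome_record(genome_id, paste(pieces, collapse = ""), taxon)
    list(genome = genome, truth = truths)
  })
}

#' Tabulate planted ground truth
#'
#' @param truth the truth list from [plant_elements()].
#' @return data.frame, one row per element.
#' @export
truth_table <- function(truth) {
  if (length(truth) == 0)
    return(data.frame(element_id = character(0), genome_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), structure = character(0),
                      domains = character(0), rh_core_state = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(truth, function(t) data.frame(
    element_id = t$element_id, genome_id = t$genome_id,
    start = t$span[1], end = t$span[2], strand = t$strand,
    structure = t$structure,
    domains = paste(t$domain_spans$domain, collapse = ","),
    rh_core_state = t$rh_core_state,
    stringsAsFactors = FALSE)))
}

#' Write genomes to FASTA
#' @param genomes a `genome_record` or list of them.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "seq"))
  names(ss) <- vapply(genomes, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read genomes from FASTA
#' @param path FASTA path.
#' @return list of [genome_record()]s.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  lapply(seq_along(ss), function(i)
    genome_record(ids[i], as.character(ss[[i]])))
}

#' Write planted truth as GFF3
#'
#' One `mobile_genetic_element` feature per element (with a `structure`
#' attribute), child `long_terminal_repeat` and `protein_match` features.
#' Coordinates are converted to GFF3's 1-based inclusive convention.
#'
#' @param truth truth list from [plant_elements()].
#' @param path output path.
#' @export
write_truth_gff3 <- function(truth, path) {
  rows <- list()
  for (t in truth) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = t$genome_id, start = t$span[1] + 1L, end = t$span[2],
      strand = t$strand, type = "mobile_genetic_element",
      ID = t$element_id, Parent = NA_character_,
      Name = t$structure, structure = t$structure, stringsAsFactors = FALSE)
    for (l in names(t$ltr_spans)) {
      sp <- t$ltr_spans[[l]]
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = t$genome_id, start = sp[1] + 1L, end = sp[2],
        strand = t$strand, type = "long_terminal_repeat",
        ID = paste0(t$element_id, "_ltr_", l), Parent = t$element_id,
        Name = paste0(l, "_prime_LTR"), structure = NA_character_,
        stringsAsFactors = FALSE)
    }
    ds <- t$domain_spans
    for (r in seq_len(nrow(ds))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = t$genome_id, start = ds$start[r] + 1L, end = ds$end[r],
        strand = t$strand, type = "protein_match",
        ID = sprintf("%s_dom%02d", t$element_id, r), Parent = t$element_id,
        Name = ds$domain[r], structure = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Name <- df$Name
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$structure <- df$structure
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
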