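# Structural-variant classification: the five aRH placements, aRH-less
# elements, and everything else as UNKNOWN.
#
# The variants are defined by where the additional RNase H sits relative to
# the native RH/RT and by ORF membership:
#   S1  gag | pol[PR RT RH aRH INT]       (retrovirus-like dual RH)
#   S2  gag | pol[PR aRH RT RH INT]       (aRH upstream of RT, inside pol)
#   S3  gag | aRH-ORF | pol[PR RT RH INT] (aRH in its own ORF upstream of pol)
#   S4  aRH-ORF | gag | pol[PR RT RH INT] (aRH ORF upstream of gag)
#   S5  gag | pol[PR RT RH aRH aRH INT]   (proximal + distal aRH)

# Maximal ATG-to-stop ORFs (>= min_orf_aa codons before the stop) in all
# three frames of a strand-oriented sequence; 0-based half-open coordinates
# including the stop codon.
find_orfs <- function(seq, min_orf_aa) {
  n <- nchar(seq)
  rows <- list()
  for (f in 1:3) {
    aa <- translate_dna(substr(seq, f, n))
    if (nchar(aa) == 0) next
    v <- chars(aa)
    stops <- which(v == "*")
    ms <- which(v == "M")
    prev <- 0L
    for (t in stops) {
      seg_ms <- ms[ms > prev & ms < t]
      if (length(seg_ms) > 0) {
        m <- seg_ms[1]
        if (t - m >= min_orf_aa) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = (f - 1L) + 3L * (m - 1L), end = (f - 1L) + 3L * t,
            frame = f, aa_len = t - m)
        }
      }
      prev <- t
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), aa_len = integer(0)))
  do.call(rbind, rows)
}

#' Assign ORF indices to the hits of a chain
#'
#' Finds maximal `ATG ... stop` open reading frames of at least `min_orf_aa`
#' codons in the (padded) chain span on the element strand, assigns each
#' domain hit to the ORF containing at least 80% of its span, and numbers the
#' hit-bearing ORFs 0, 1, ... in element 5' to 3' order. Hits contained in no
#' ORF keep `NA`.
#'
#' @param genome a [genome_record()].
#' @param chain an `element_chain` mined from this genome.
#' @param min_orf_aa minimum ORF length in codons.
#' @param pad bp of context added around the chain span so the initiator ATG
#'   and terminal stop (which sit just outside the outermost hits) are seen.
#' @return the chain with `hits$orf` filled and `orf_spans` attached.
#' @export
assign_orfs <- function(genome, chain, min_orf_aa = 60, pad = 300) {
  if (nrow(chain$hits) == 0) return(chain)
  n <- nchar(genome$seq)
  rs <- max(0L, chain$span[1] - pad)
  re <- min(n, chain$span[2] + pad)
  sub <- substr(genome$seq, rs + 1, re)
  if (chain$strand == "-") sub <- revcomp(sub)
  orfs <- find_orfs(sub, min_orf_aa)
  if (nrow(orfs) > 0) {
    lr <- re - rs
    if (chain$strand == "+") {
      gs <- rs + orfs$start; ge <- rs + orfs$end
    } else {
      gs <- rs + lr - orfs$end; ge <- rs + lr - orfs$start
    }
    orfs$gstart <- gs; orfs$gend <- ge
  }
  h <- chain$hits
  h$orf <- NA_integer_
  if (nrow(orfs) > 0) {
    assigned <- integer(nrow(h))
    for (i in seq_len(nrow(h))) {
      ov <- vapply(seq_len(nrow(orfs)), function(j)
        interval_overlap(h$start[i], h$end[i], orfs$gstart[j], orfs$gend[j]),
        numeric(1))
      j <- which.max(ov)
      assigned[i] <- if (length(ov) && ov[j] >= 0.8 * (h$end[i] - h$start[i]))
        j else NA_integer_
    }
    used <- sort(unique(assigned[!is.na(assigned)]))
    if (length(used) > 0) {
      uo <- orfs[used, , drop = FALSE]
      eo <- if (chain$strand == "+") rank(uo$gstart) else rank(-uo$gstart)
      idx0 <- as.integer(eo) - 1L  # element-order 0-based ORF index
      h$orf <- idx0[match(assigned, used)]
      o <- order(idx0)
      chain$orf_spans <- data.frame(orf = idx0[o], start = uo$gstart[o],
                                    end = uo$gend[o])
    }
  }
  chain$hits <- h
  chain
}

structure_call <- function(label, rationale) {
  structure(list(label = label, rationale = rationale),
            class = "structure_call")
}

#' @export
print.structure_call <- function(x, ...) {
  cat(sprintf("<structure_call %s: %s>\n", x$label, x$rationale))
  invisible(x)
}

#' Classify the structural variant of a chain
#'
#' Rules are evaluated in order on the element-ordered domains (ORF indices
#' must be assigned first, see [assign_orfs()]): no aRH gives `NO_ARH`; two
#' contiguous aRHs after the native RH inside pol give `S5`; one aRH
#' immediately after the native RH inside pol gives `S1`; one aRH before RT
#' inside pol gives `S2`; one aRH alone in its own ORF between gag and pol
#' gives `S3`, or before gag gives `S4`; anything else is `UNKNOWN`. A chain
#' with aRH but without a native RT or RH is `UNKNOWN` (the variants are
#' defined relative to the native domains).
#'
#' @param chain an `element_chain` with ORF indices.
#' @param arh_linker maximum bp tolerated between the native RH (or the first
#'   aRH) and the following aRH for the "immediately after" rules.
#' @return a `structure_call` (fields `label`, `rationale`).
#' @export
classify_structure <- function(chain, arh_linker = 600) {
  d <- chain$hits
  if (nrow(d) == 0)
    return(structure_call("UNKNOWN", "empty chain"))
  # classification depends only on element order, never on insertion order
  ord <- if (chain$strand == "-") order(-d$start) else order(d$start)
  d <- d[ord, , drop = FALSE]
  gap_after <- function(i) {  # genomic gap between element-consecutive hits
    if (chain$strand == "+") d$start[i + 1] - d$end[i]
    else d$start[i] - d$end[i + 1]
  }
  arh <- which(d$domain == "ARH")
  if (length(arh) == 0)
    return(structure_call("NO_ARH", "no aRH domain detected"))
  rt <- which(d$domain == "RT")
  rh <- which(d$domain == "RH")
  gag <- which(d$domain == "GAG")
  if (length(rt) == 0 || length(rh) == 0)
    return(structure_call("UNKNOWN",
                          "aRH present but native RT/RH missing"))
  if (any(is.na(d$orf[arh])))
    return(structure_call("UNKNOWN", "aRH hit not contained in an ORF"))
  pol_orf <- d$orf[rt[1]]
  rh1 <- rh[1]
  own_orf <- function(i) {
    !is.na(d$orf[i]) && sum(d$orf == d$orf[i], na.rm = TRUE) == 1
  }
  if (length(arh) == 2 && all(arh > rh1) && arh[2] == arh[1] + 1 &&
      all(d$orf[arh] == pol_orf) && gap_after(arh[1]) <= arh_linker)
    return(structure_call("S5",
      "two sequential aRH domains after the native RH within pol"))
  if (length(arh) == 1) {
    a <- arh[1]
    if (a == rh1 + 1 && d$orf[a] == pol_orf && gap_after(rh1) <= arh_linker)
      return(structure_call("S1",
        "single aRH immediately after the native RH within pol"))
    if (a < rt[1] && d$orf[a] == pol_orf)
      return(structure_call("S2", "single aRH upstream of RT within pol"))
    if (own_orf(a) && length(gag) > 0) {
      pol_rows <- which(d$orf == pol_orf)
      if (a > gag[1] && length(pol_rows) > 0 && a < min(pol_rows))
        return(structure_call("S3",
          "aRH in its own ORF between gag and pol"))
      if (a < gag[1])
        return(structure_call("S4", "aRH in its own ORF upstream of gag"))
    }
  }
  structure_call("UNKNOWN", "no structure rule matched")
}

#' Classify a list of chains
#'
#' @param chains list of `element_chain`s with ORF indices assigned.
#' @param arh_linker see [classify_structure()].
#' @return data.frame with `element_id`, `genome`, `label`, `rationale`.
#' @export
classify_chains <- function(chains, arh_linker = 600) {
  if (length(chains) == 0)
    return(data.frame(element_id = character(0), genome = character(0),
                      label = character(0), rationale = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(chains, function(ch) {
    sc <- classify_structure(ch, arh_linker = arh_linker)
    data.frame(element_id = ch$id, genome = ch$genome, label = sc$label,
               rationale = sc$rationale, stringsAsFactors = FALSE)
  }))
}

#' Per-genome structure frequency table
#'
#' Counts and percentages (1 decimal) per structure label and genome;
#' percentages are over all classified elements including `UNKNOWN`.
#'
#' @param calls data.frame with columns `genome` and `label`.
#' @return data.frame with `genome`, `label`, `n`, `pct`.
#' @export
structure_frequency_table <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(genome = character(0), label = character(0),
                      n = integer(0), pct = numeric(0),
                      stringsAsFactors = FALSE))
  out <- list()
  for (g in unique(calls$genome)) {
    lab <- calls$label[calls$genome == g]
    tab <- table(lab)
    out[[g]] <- data.frame(genome = g, label = names(tab),
                           n = as.integer(tab),
                           pct = round(100 * as.integer(tab) / length(lab), 1),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
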