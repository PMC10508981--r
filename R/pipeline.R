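# Pipeline orchestration: simulate -> annotate -> report, with a JSON config,
# derived seeds, stderr logging and a markdown run report.

#' Default run configuration
#'
#' All thresholds used anywhere in the pipeline, in one (serializable) list.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_genomes = 1L,
      genome_length = 200000L,
      gc = 0.4,
      elements_per_genome = 6L,
      structures = c("S1", "S2", "S3", "S4", "S5", "NO_ARH"),
      ltr_length = 300L,
      ltr_divergence = 0.05,
      domain_divergence = 0.05,
      degrade_native_rh = TRUE,
      degrade_distal_arh = TRUE,
      int_position = "last",
      margin = 6000L,
      min_gap = 15000L,
      library_seed = 42L,
      taxa = NULL
    ),
    mining = list(
      min_bits_frac = 0.4,
      max_gap = 10000L,
      flank = 5000L,
      ltr_min_len = 100L,
      ltr_min_identity = 80
    ),
    classify = list(min_orf_aa = 60L, arh_linker = 600L),
    degradation = list(degraded_threshold = 1L),
    phylo = list(
      identity_threshold = 80,
      support_threshold = 95,
      n_reps = 100L,
      distance_correction = "none"
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate a run configuration
#' @param config nested list as from [default_config()].
#' @return the config, invisibly; raises a config error on violations.
#' @export
validate_config <- function(config) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop_config(msg)
  s <- config$simulate; m <- config$mining; p <- config$phylo
  chk(s$gc > 0 && s$gc < 1, "simulate.gc must be in (0, 1)")
  chk(s$ltr_divergence >= 0 && s$ltr_divergence <= 0.5,
      "simulate.ltr_divergence must be in [0, 0.5]")
  chk(s$domain_divergence >= 0 && s$domain_divergence <= 0.5,
      "simulate.domain_divergence must be in [0, 0.5]")
  chk(all(s$structures %in% c("S1", "S2", "S3", "S4", "S5", "NO_ARH")),
      "simulate.structures must be structure labels")
  chk(s$int_position %in% c("last", "after_pr"),
      "simulate.int_position must be 'last' or 'after_pr'")
  chk(m$min_bits_frac > 0 && m$min_bits_frac <= 1,
      "mining.min_bits_frac must be in (0, 1]")
  chk(m$flank >= m$ltr_min_len, "mining.flank must be >= ltr_min_len")
  chk(m$ltr_min_identity > 0 && m$ltr_min_identity <= 100,
      "mining.ltr_min_identity must be a percentage")
  chk(p$support_threshold > 0 && p$support_threshold <= 100,
      "phylo.support_threshold must be a percentage")
  chk(p$n_reps >= 1, "phylo.n_reps must be >= 1")
  chk(config$classify$min_orf_aa >= 1, "classify.min_orf_aa must be >= 1")
  chk(config$degradation$degraded_threshold %in% 1:4,
      "degradation.degraded_threshold must be 1..4")
  invisible(config)
}

#' Read a configuration file (JSON)
#'
#' Values round-trip losslessly through [write_config()]; missing fields fall
#' back to [default_config()].
#'
#' @param path JSON file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config(paste("config file not found:", path))
  override <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- merge_config(default_config(), override)
  if (length(cfg$simulate$taxa) == 0) cfg$simulate["taxa"] <- list(NULL)
  validate_config(cfg)
}

#' Write a configuration file (JSON)
#' @param config config list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

rtt_log <- function(fmt, ..., logfile = NULL) {
  msg <- sprintf("[retrotether] %s", sprintf(fmt, ...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Simulate genomes with planted elements
#'
#' Writes `genomes.fasta`, `truth.gff3`, `truth.tsv` and a scannable profile
#' library under `profiles/` to `out_dir`.
#'
#' @param config validated config list.
#' @param out_dir output directory.
#' @return list with `genomes`, `truth` (per genome) and `library`, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  s <- config$simulate
  lib <- make_profile_library(s$library_seed)
  profiles <- profiles_from_specs(lib, seed = derive_seed(config$seed, 1000))
  write_profile_library(profiles, file.path(out_dir, "profiles"))
  genomes <- list(); truths <- list()
  for (g in seq_len(s$n_genomes)) {
    labels <- rep_len(s$structures, s$elements_per_genome)
    bps <- lapply(seq_along(labels), function(i)
      element_blueprint(labels[i], ltr_length = s$ltr_length,
                        ltr_divergence = s$ltr_divergence,
                        domain_divergence = s$domain_divergence,
                        degrade_native_rh = s$degrade_native_rh &&
                          labels[i] != "NO_ARH",
                        degrade_distal_arh = s$degrade_distal_arh &&
                          labels[i] == "S5",
                        seed = derive_seed(config$seed, g, i)))
    taxon <- if (length(s$taxa) >= g) s$taxa[[g]] else NA_character_
    sim <- plant_elements(s$genome_length, bps, lib, gc = s$gc,
                          seed = derive_seed(config$seed, g),
                          genome_id = sprintf("genome%02d", g), taxon = taxon,
                          margin = s$margin, min_gap = s$min_gap,
                          int_position = s$int_position)
    genomes[[g]] <- sim$genome
    truths[[g]] <- sim$truth
    rtt_log("simulated %s: %d bp, %d planted elements", sim$genome$id,
            nchar(sim$genome$seq), length(sim$truth), logfile = logfile)
  }
  write_genome_fasta(genomes, file.path(out_dir, "genomes.fasta"))
  all_truth <- do.call(c, truths)
  write_truth_gff3(all_truth, file.path(out_dir, "truth.gff3"))
  utils::write.table(truth_table(all_truth), file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genomes = genomes, truth = truths, library = lib,
                 profiles = profiles))
}

chain_table <- function(chains, calls) {
  if (length(chains) == 0)
    return(data.frame(element_id = character(0), genome = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), domains = character(0),
                      ltr_found = logical(0), ltr_identity = numeric(0),
                      ltr_length = integer(0), edge_truncated = logical(0),
                      completeness = numeric(0), label = character(0),
                      rationale = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(chains, function(ch) data.frame(
    element_id = ch$id, genome = ch$genome, start = ch$span[1],
    end = ch$span[2], strand = ch$strand,
    domains = paste(ch$hits$domain, collapse = ","),
    ltr_found = !is.null(ch$ltr),
    ltr_identity = if (is.null(ch$ltr)) NA_real_ else round(ch$ltr$identity, 1),
    ltr_length = if (is.null(ch$ltr)) NA_integer_ else ch$ltr$length,
    edge_truncated = ch$edge_truncated,
    completeness = ch$completeness, stringsAsFactors = FALSE)))
  merge(df, calls[, c("element_id", "label", "rationale")],
        by = "element_id", sort = TRUE)
}

write_annotation_gff3 <- function(chains, calls, path) {
  rows <- list()
  lab <- stats::setNames(calls$label, calls$element_id)
  for (ch in chains) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = ch$genome, start = ch$span[1] + 1L, end = ch$span[2],
      strand = ch$strand, type = "mobile_genetic_element", ID = ch$id,
      Parent = "", Name = unname(lab[ch$id]),
      structure = unname(lab[ch$id]), stringsAsFactors = FALSE)
    if (!is.null(ch$ltr)) {
      for (side in names(ch$ltr$spans)) {
        sp <- ch$ltr$spans[[side]]
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = ch$genome, start = sp[1] + 1L, end = sp[2],
          strand = ch$strand, type = "long_terminal_repeat",
          ID = paste0(ch$id, "_ltr_", side), Parent = ch$id,
          Name = paste0(side, "stream_LTR"), structure = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    for (r in seq_len(nrow(ch$hits))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = ch$genome, start = ch$hits$start[r] + 1L,
        end = ch$hits$end[r], strand = ch$strand, type = "protein_match",
        ID = sprintf("%s_dom%02d", ch$id, r), Parent = ch$id,
        Name = ch$hits$domain[r], structure = NA_character_,
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
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$structure <- df$structure
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

write_domain_fasta <- function(chains, path) {
  seqs <- character(0)
  for (ch in chains) {
    h <- ch$hits
    if (nrow(h) == 0) next
    dn <- h$domain
    for (d in unique(dn[duplicated(dn)])) {
      at <- which(dn == d)
      dn[at[-1]] <- sprintf("%s.%d", d, seq_along(at[-1]) + 1L)
    }
    hdr <- sprintf("%s|%s|%s|%d-%d|%s", ch$id, dn, ch$genome,
                   h$start, h$end, ch$strand)
    seqs[hdr] <- h$aaseq
  }
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Annotate genomes: mine, assign ORFs, classify, assess RH cores
#'
#' Writes `chains.tsv`, `annotation.gff3`, `domains.fasta` and
#' `rh_assessments.tsv` to `out_dir`.
#'
#' @param config validated config list.
#' @param genome_fasta path to the genome FASTA.
#' @param profiles_dir profile library directory
#'   (see [write_profile_library()]).
#' @param out_dir output directory.
#' @return list with `chains`, `calls`, `assessments`, `table`, invisibly.
#' @export
cmd_annotate <- function(config, genome_fasta, profiles_dir, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  m <- config$mining
  profiles <- read_profile_library(profiles_dir)
  thr <- vapply(profiles, profile_self_score, numeric(1)) * m$min_bits_frac
  rtt_log("thresholds (bits): %s",
          paste(sprintf("%s=%.1f", names(thr), thr), collapse = ", "),
          logfile = logfile)
  rtt_log("max_gap=%d flank=%d ltr_min_len=%d ltr_min_identity=%s min_orf_aa=%d arh_linker=%d degraded_threshold=%d",
          m$max_gap, m$flank, m$ltr_min_len, format(m$ltr_min_identity),
          config$classify$min_orf_aa, config$classify$arh_linker,
          config$degradation$degraded_threshold, logfile = logfile)
  genomes <- read_genome_fasta(genome_fasta)
  all_chains <- list()
  assessments <- list()
  for (gn in genomes) {
    mined <- mine_genome(gn, profiles, min_bits = thr, max_gap = m$max_gap,
                         flank = m$flank, ltr_min_len = m$ltr_min_len,
                         ltr_min_identity = m$ltr_min_identity)
    chains <- lapply(mined$chains, assign_orfs, genome = gn,
                     min_orf_aa = config$classify$min_orf_aa)
    rtt_log("%s: %d hits, %d chains", gn$id, nrow(mined$hits),
            length(chains), logfile = logfile)
    all_chains <- c(all_chains, chains)
    for (ch in chains)
      assessments[[length(assessments) + 1L]] <-
        assess_chain_rh(ch, profiles,
                        degraded_threshold = config$degradation$degraded_threshold)
  }
  calls <- classify_chains(all_chains,
                           arh_linker = config$classify$arh_linker)
  assess <- if (length(assessments)) do.call(rbind, assessments)
            else data.frame(element_id = character(0), genome = character(0),
                            domain = character(0), role = character(0),
                            core_state = character(0),
                            intact_count = integer(0), severity = integer(0),
                            degraded = logical(0), stringsAsFactors = FALSE)
  tab <- chain_table(all_chains, calls)
  utils::write.table(tab, file.path(out_dir, "chains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(assess, file.path(out_dir, "rh_assessments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotation_gff3(all_chains, calls,
                        file.path(out_dir, "annotation.gff3"))
  write_domain_fasta(all_chains, file.path(out_dir, "domains.fasta"))
  invisible(list(chains = all_chains, calls = calls, assessments = assess,
                 table = tab))
}

read_domain_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  data.frame(element_id = vapply(parts, `[`, character(1), 1),
             domain = vapply(parts, `[`, character(1), 2),
             genome = vapply(parts, `[`, character(1), 3),
             aaseq = as.character(ss), stringsAsFactors = FALSE)
}

md_table <- function(df) {
  if (nrow(df) == 0) return("(empty)")
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r)
    paste0("| ", paste(format(r, trim = TRUE), collapse = " | "), " |"))
  paste(c(hdr, sep, body), collapse = "\n")
}

#' Aggregate annotation outputs into a run report
#'
#' Produces the per-genome structure frequency table, the degradation summary
#' per (structure, role), RT / INT / concatenated bootstrap trees (newick),
#' the aRH-clade monophyly test, the two-of-three lineage filter decisions,
#' the Fitch parsimony scenario when a species tree is supplied, and a single
#' markdown report.
#'
#' @param config validated config list.
#' @param annot_dir directory written by [cmd_annotate()].
#' @param out_dir output directory.
#' @param species_tree optional newick path (tips = taxon groups).
#' @param taxon_map optional TSV path with columns `genome`, `taxon_group`.
#' @return list with the computed tables/trees, invisibly.
#' @export
cmd_report <- function(config, annot_dir, out_dir, species_tree = NULL,
                       taxon_map = NULL) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  tab <- utils::read.table(file.path(annot_dir, "chains.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  assess <- utils::read.table(file.path(annot_dir, "rh_assessments.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  doms <- read_domain_fasta(file.path(annot_dir, "domains.fasta"))
  p <- config$phylo

  freq <- structure_frequency_table(tab[, c("genome", "label")])
  utils::write.table(freq, file.path(out_dir, "structure_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  assess <- merge(assess, tab[, c("element_id", "label")], by = "element_id")
  names(assess)[names(assess) == "label"] <- "structure"
  degr <- degradation_report(assess)
  utils::write.table(degr, file.path(out_dir, "degradation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tmap <- if (!is.null(taxon_map))
    utils::read.table(taxon_map, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else data.frame(genome = unique(tab$genome),
                  taxon_group = unique(tab$genome), stringsAsFactors = FALSE)

  trees <- list(); mono <- NULL; clusters <- list(); filt <- NULL
  aln <- list()
  for (dom in c("RT", "INT")) {
    ds <- doms[doms$domain == dom, , drop = FALSE]
    ds <- ds[!duplicated(ds$element_id), , drop = FALSE]
    if (nrow(ds) >= 3) {
      a <- progressive_align(stats::setNames(ds$aaseq, ds$element_id))
      aln[[dom]] <- a
      trees[[dom]] <- bootstrap_support(a, n_reps = p$n_reps,
                                        seed = derive_seed(config$seed, 77,
                                                           match(dom, c("RT", "INT"))))
      ape::write.tree(trees[[dom]],
                      file.path(out_dir, sprintf("%s_tree.nwk", tolower(dom))))
    }
  }
  if (all(c("RT", "INT") %in% names(aln)) &&
      length(intersect(names(aln$RT), names(aln$INT))) >= 3) {
    cc <- concat_alignment(aln$RT, aln$INT)
    trees$concat <- bootstrap_support(cc, n_reps = p$n_reps,
                                      seed = derive_seed(config$seed, 77, 3))
    ape::write.tree(trees$concat, file.path(out_dir, "concat_tree.nwk"))
  }
  if (!is.null(trees$RT)) {
    arh_tips <- intersect(trees$RT$tip.label,
                          tab$element_id[tab$label %in% paste0("S", 1:5)])
    if (length(arh_tips) >= 1 &&
        length(arh_tips) < length(trees$RT$tip.label))
      mono <- test_monophyly(trees$RT, arh_tips)
    clusters <- credible_clusters(trees$RT, threshold = p$support_threshold)
    lin <- merge(tab, tmap, by = "genome", all.x = TRUE)
    lin$taxon_group[is.na(lin$taxon_group)] <- lin$genome[is.na(lin$taxon_group)]
    lineages <- data.frame(lineage = lin$element_id,
                           taxon_group = lin$taxon_group,
                           structure = lin$label,
                           whole_contig_or_no_ltr =
                             lin$edge_truncated | !lin$ltr_found,
                           stringsAsFactors = FALSE)
    lineages <- lineages[lineages$lineage %in% trees$RT$tip.label, ,
                         drop = FALSE]
    filt <- filter_lineages(lineage_flags(lineages, clusters))
    utils::write.table(filt$flags, file.path(out_dir, "lineage_filter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  scenario <- NULL
  if (!is.null(species_tree)) {
    sp <- ape::read.tree(species_tree)
    lin <- merge(tab, tmap, by = "genome", all.x = TRUE)
    states <- lapply(split(lin$label, lin$taxon_group), function(x)
      sort(unique(setdiff(x, "UNKNOWN"))))
    states <- states[vapply(states, length, integer(1)) > 0]
    usable <- intersect(sp$tip.label, names(states))
    if (length(usable) >= 2 &&
        length(usable) < length(sp$tip.label)) {
      sp <- ape::drop.tip(sp, setdiff(sp$tip.label, usable))
    }
    if (!is.null(sp) && all(sp$tip.label %in% names(states)) &&
        length(sp$tip.label) >= 2 && ape::is.binary(sp)) {
      scenario <- fitch_parsimony(sp, states)
      scenario$root_states <- scenario$states[[length(sp$tip.label) + 1L]]
      rtt_log("parsimony scenario: %d changes", scenario$changes,
              logfile = logfile)
    } else {
      rtt_log("species tree unusable for parsimony; section omitted",
              logfile = logfile)
    }
  }

  rep_path <- file.path(out_dir, "report.md")
  lines <- c(
    "# retrotether run report", "",
    sprintf("Seed: %d. Support threshold: %s. Bootstrap replicates: %d.",
            config$seed, format(p$support_threshold), p$n_reps),
    "", "## Structure frequencies per genome", "", md_table(freq), "",
    "## Catalytic-core degradation by structure and domain role", "",
    md_table(degr), "")
  if (!is.null(mono))
    lines <- c(lines, "## aRH-clade monophyly (RT tree)", "",
               sprintf("Monophyletic: %s; defining-edge support: %s",
                       mono$monophyletic, format(mono$support)), "")
  if (!is.null(filt))
    lines <- c(lines, "## Lineage credibility filter (2 of 3 rule)", "",
               md_table(filt$flags), "")
  if (!is.null(scenario)) {
    lines <- c(lines, "## Minimal rearrangement scenario (Fitch parsimony)",
               "", sprintf("Minimum structure changes on the species tree: %d",
                           scenario$changes),
               sprintf("Fitch state set at the root: {%s}",
                       paste(scenario$root_states, collapse = ", ")), "")
  }
  writeLines(lines, rep_path)
  invisible(list(frequencies = freq, degradation = degr, trees = trees,
                 monophyly = mono, clusters = clusters, filter = filt,
                 scenario = scenario, report = rep_path))
}

#' Run the full pipeline
#'
#' @param config validated config list.
#' @param out_dir output directory (subdirectories `simulate/`, `annotate/`,
#'   `report/`).
#' @param species_tree,taxon_map passed to [cmd_report()].
#' @return list of the three stage results, invisibly.
#' @export
run_all <- function(config, out_dir, species_tree = NULL, taxon_map = NULL) {
  sim <- cmd_simulate(config, file.path(out_dir, "simulate"))
  ann <- cmd_annotate(config, file.path(out_dir, "simulate", "genomes.fasta"),
                      file.path(out_dir, "simulate", "profiles"),
                      file.path(out_dir, "annotate"))
  rep <- cmd_report(config, file.path(out_dir, "annotate"),
                    file.path(out_dir, "report"),
                    species_tree = species_tree, taxon_map = taxon_map)
  invisible(list(simulate = sim, annotate = ann, report = rep))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `annotate`, `report`, `run-all`. Exit status 0 on
#' success, 2 on configuration/capacity errors, 1 otherwise.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status.
#' @export
rtt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 ||
      !args[1] %in% c("simulate", "annotate", "report", "run-all")) {
    message("usage: retrotether <simulate|annotate|report|run-all> [options]")
    return(2L)
  }
  sub <- args[1]
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--genome", type = "character", default = NULL),
    optparse::make_option("--profiles", type = "character", default = NULL),
    optparse::make_option("--out-dir", type = "character", default = "out",
                          dest = "out_dir"),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--threads", type = "integer", default = 1L),
    optparse::make_option("--species-tree", type = "character",
                          default = NULL, dest = "species_tree"),
    optparse::make_option("--taxon-map", type = "character", default = NULL,
                          dest = "taxon_map"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args[-1])
  tryCatch({
    config <- if (!is.null(opt$config)) read_config(opt$config)
              else validate_config(default_config())
    if (!is.null(opt$seed)) config$seed <- opt$seed
    switch(sub,
      "simulate" = cmd_simulate(config, opt$out_dir),
      "annotate" = {
        if (is.null(opt$genome) || is.null(opt$profiles))
          stop_config("annotate needs --genome and --profiles")
        cmd_annotate(config, opt$genome, opt$profiles, opt$out_dir)
      },
      "report" = {
        if (is.null(opt$genome))
          stop_config("report needs --genome pointing at the annotate output directory")
        cmd_report(config, opt$genome, opt$out_dir,
                   species_tree = opt$species_tree,
                   taxon_map = opt$taxon_map)
      },
      "run-all" = run_all(config, opt$out_dir,
                          species_tree = opt$species_tree,
                          taxon_map = opt$taxon_map))
    0L
  }, rtt_config_error = function(e) {
    message("config error: ", conditionMessage(e)); 2L
  }, rtt_capacity_error = function(e) {
    message("capacity error: ", conditionMessage(e)); 2L
  }, error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
}
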