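fake_hits <- function(starts, strand = "+", domain = NULL, genome = "g1",
                      width = 390) {
  k <- length(starts)
  if (is.null(domain)) domain <- rep_len(c("GAG", "RT", "INT"), k)
  data.frame(domain = domain, genome = genome, strand = strand,
             start = starts, end = starts + width, frame = 1L,
             score = 100 + seq_len(k), aaseq = strrep("A", width / 3),
             stringsAsFactors = FALSE)
}

test_that("chain_hits links by gap and splits distant groups", {
  h <- fake_hits(c(1000, 3000, 5000))
  ch <- chain_hits(h, max_gap = 5000)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$hits), 3)

  h2 <- rbind(h, fake_hits(c(1000, 3000, 5000) + 100000))
  ch2 <- chain_hits(h2, max_gap = 5000)
  expect_length(ch2, 2)

  # minus-strand chains are ordered element 5'->3' (descending start)
  h3 <- fake_hits(c(1000, 3000, 5000), strand = "-")
  ch3 <- chain_hits(h3, max_gap = 5000)
  expect_equal(ch3[[1]]$hits$start, c(5000, 3000, 1000))

  # overlapping same-profile hits resolve to the higher score
  h4 <- fake_hits(c(1000, 1100), domain = c("RT", "RT"))
  ch4 <- chain_hits(h4, max_gap = 5000)
  expect_equal(nrow(ch4[[1]]$hits), 1)
  expect_equal(ch4[[1]]$hits$start, 1100)  # score 102 > 101

  expect_error(chain_hits(rbind(h, fake_hits(2000, genome = "g2")), 1000),
               class = "rtt_parameter_error")
})

test_that("find_ltrs recovers planted pairs and respects edges", {
  lib <- fixture_library()
  sim0 <- plant_elements(40000, make_blueprints("S1", seed0 = 60), lib,
                         seed = 8, min_gap = 0, margin = 8000)
  t <- sim0$truth[[1]]
  ch <- chain_hits(fake_hits(t$domain_spans$start[2],
                             domain = "RT", strand = t$strand))[[1]]
  ch$span <- c(min(t$domain_spans$start), max(t$domain_spans$end))
  lt <- find_ltrs(sim0$genome, ch)
  expect_true(lt$found)
  expect_equal(lt$identity, 100)
  expect_gte(lt$length, 295)
  expect_lte(lt$length, 315)
  # reported spans cover the planted LTRs
  expect_lte(abs(lt$spans$up[1] - min(t$ltr_spans$five[1],
                                      t$ltr_spans$three[1])), 10)

  # chain too close to the contig edge: flagged, no LTR
  ch_edge <- ch
  ch_edge$span <- c(1000, 4000)
  lt2 <- find_ltrs(sim0$genome, ch_edge)
  expect_false(lt2$found)
  expect_true(lt2$edge_truncated)
  expect_error(find_ltrs(sim0$genome, ch, flank = 50, min_len = 100),
               class = "rtt_parameter_error")
})

test_that("diverged LTR pairs report calibrated identity", {
  lib <- fixture_library()
  sim <- plant_elements(40000, make_blueprints("S1", ltr_div = 0.05,
                                               seed0 = 61),
                        lib, seed = 9, min_gap = 0, margin = 8000)
  t <- sim$truth[[1]]
  ch <- chain_hits(fake_hits(t$domain_spans$start[2], domain = "RT",
                             strand = t$strand))[[1]]
  ch$span <- c(min(t$domain_spans$start), max(t$domain_spans$end))
  lt <- find_ltrs(sim$genome, ch)
  expect_true(lt$found)
  # oracle: Hamming identity of the planted (substitution-only) LTR copies
  l5 <- substr(sim$genome$seq, t$ltr_spans$five[1] + 1, t$ltr_spans$five[2])
  l3 <- substr(sim$genome$seq, t$ltr_spans$three[1] + 1, t$ltr_spans$three[2])
  oracle <- 100 * mean(strsplit(l5, "")[[1]] == strsplit(l3, "")[[1]])
  expect_lte(abs(lt$identity - oracle), 1.5)
  expect_gte(lt$identity, 92)
  expect_lte(lt$identity, 98)
})

test_that("pure background yields no LTR calls", {
  # scaled down from the spec's 100-seed simulation: 40 seeds, 2 kb flanks
  lib <- fixture_library()
  found <- vapply(1:40, function(i) {
    g <- plant_elements(9000, list(), lib, seed = 900 + i)$genome
    ch <- chain_hits(fake_hits(4200, domain = "RT", width = 600))[[1]]
    find_ltrs(g, ch, flank = 2000, min_len = 100, min_identity = 80)$found
  }, logical(1))
  expect_lte(sum(found), 1)  # false-positive rate at most ~1 in 40
})

test_that("completeness_score follows the declared formula", {
  all5 <- chain_hits(fake_hits(seq(1000, by = 700, length.out = 5),
                               domain = c("GAG", "PR", "RT", "RH", "INT")))[[1]]
  expect_equal(completeness_score(all5), 0.8)
  all5$ltr <- list(found = TRUE)
  expect_equal(completeness_score(all5), 1.0)
  rt_only <- chain_hits(fake_hits(1000, domain = "RT"))[[1]]
  expect_equal(completeness_score(rt_only), 0.16)
  # ARH is not a core domain
  with_arh <- chain_hits(fake_hits(c(1000, 1700), domain = c("RT", "ARH")))[[1]]
  expect_equal(completeness_score(with_arh), 0.16)
})

test_that("precluster_by_rt groups by identity and picks representatives", {
  rt <- fixture_library()$RT$consensus
  mk <- function(id, seq, complete = 0.5, span = 5000) {
    ch <- chain_hits(fake_hits(1000, domain = "RT", width = 600))[[1]]
    ch$id <- id
    ch$hits$aaseq <- seq
    ch$span <- c(1000, 1000 + span)
    ch$completeness <- complete
    ch
  }
  # identical RT: one cluster, representative = higher completeness
  cl <- precluster_by_rt(list(mk("a", rt, 0.5), mk("b", rt, 0.9)), 90)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$representative, "b")
  # unrelated RT at threshold 90: two singletons
  other <- withr::with_seed(2, paste(sample(retrotether:::AA20, nchar(rt),
                                            TRUE), collapse = ""))
  cl2 <- precluster_by_rt(list(mk("a", rt), mk("b", other)), 90)
  expect_length(cl2, 2)
  # 10 mutated copies at 5% divergence, threshold 80: one cluster
  copies <- withr::with_seed(31, lapply(1:10, function(i)
    mk(sprintf("c%02d", i), retrotether:::.mutate_protein(rt, 0.05))))
  cl3 <- precluster_by_rt(copies, 80)
  expect_length(cl3, 1)
  expect_length(cl3[[1]]$members, 10)
  # chains lacking RT pass through flagged
  no_rt <- chain_hits(fake_hits(1000, domain = "GAG"))[[1]]
  no_rt$id <- "z"
  cl4 <- precluster_by_rt(list(no_rt, mk("a", rt)), 90)
  expect_length(cl4, 2)
  expect_false(cl4[[1]]$has_rt)
})

test_that("mined six-structure genome recovers every planted domain", {
  fx <- fixture_mined()
  truth <- fx$sim$truth
  matched <- match_chains_to_truth(fx$chains, truth)
  for (i in seq_along(truth)) {
    expect_false(is.null(matched[[i]]))
    expect_identical(matched[[i]]$hits$domain, truth[[i]]$domain_spans$domain)
    expect_identical(matched[[i]]$strand, truth[[i]]$strand)
    expect_true(matched[[i]]$ltr$found)
    expect_gte(matched[[i]]$ltr$identity, 98)  # zero LTR divergence planted
  }
})
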