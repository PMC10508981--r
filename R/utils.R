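# Shared constants and small helpers.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA4 <- c("A", "C", "G", "T")

# Residues used to replace a catalytic carboxylate when a core is degraded:
# small/polar residues seen at degenerated positions, never D or E so a
# degraded position can not read as conservatively swapped.
DEGRADED_RESIDUES <- c("A", "N", "S", "T", "G")

STRUCTURE_LABELS <- c("S1", "S2", "S3", "S4", "S5", "NO_ARH", "UNKNOWN")

rtt_stop <- function(msg, class) {
  stop(structure(class = c(class, "rtt_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_parameter <- function(msg) rtt_stop(msg, "rtt_parameter_error")
stop_capacity  <- function(msg) rtt_stop(msg, "rtt_capacity_error")
stop_format    <- function(msg) rtt_stop(msg, "rtt_format_error")
stop_config    <- function(msg) rtt_stop(msg, "rtt_config_error")

#' Derive a reproducible child seed
#'
#' Mixes a master seed with one or more integer tags through a
#' linear-congruential step so that every stochastic stage of the pipeline
#' draws from its own stream. Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param ... integer tags identifying the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.numeric(seed) %% m
  for (k in c(...)) {
    x <- (x * 48271 + (as.numeric(k) + 1) * 2654435) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA4, n, replace = TRUE, prob = p[DNA4]), collapse = "")
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

translate_dna <- function(dna) {
  n <- nchar(dna)
  n3 <- n - n %% 3
  if (n3 < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1, n3)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

# 0-based half-open interval overlap length
interval_overlap <- function(s1, e1, s2, e2) {
  max(0, min(e1, e2) - max(s1, s2))
}
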