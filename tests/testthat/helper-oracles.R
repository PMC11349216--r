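# Independent oracles and shared fixtures. Everything here is deliberately
# naive: brute force over all offsets / subsets, no sharing with the
# implementation under test.

# The published Table-style strings, assembled literally in code.
ref_rna <- paste0(
  "CGGGUCGGAGUUAGCUCAAGCGGUUACCUCCUCAUGCCGGACUUUCUAUCUGUCCAUCUCU",
  "GUGCUGGGGUUCGAGACCCGCGGGUGCUUACUGACCCUUUU"
)
gsp_adaptor <- "CGGAGATGTGTATAAGAGACAG"
gsp_fb <- "GTATGTCCGCTCGAT"
gsp_anchor <- "AGGGTCAGTAAGCACCCGCG"
gsp_oligo_printed <- paste0(gsp_adaptor, strrep("N", 10), gsp_fb,
                            strrep("N", 9), gsp_anchor)
amplified_top_printed <- paste0(
  "CTACACGACGCTCTTCCGATCT", strrep("N", 16), strrep("N", 10),
  "TTTCTTATATGGG",
  "CGGGTCGGAGTTAGCTCAAGCGGTTACCTCCTCATGCCGGACTTTCTATCTGTCCATCTCT",
  "GTGCTGGGGTTCGAGACCCGCGGGTGCTTACTGACCCT",
  strrep("N", 9), "ATCGAGCGGACATAC", strrep("N", 10),
  "CTGTCTCTTATACACATCTCCG"
)
library_top_printed <- paste0("ACACTCTTTCCC", amplified_top_printed,
                              "AGCCCACGAGAC")
# first-strand cDNA as printed 3'->5' in the reference table
first_strand_printed_35 <- paste0(
  "CCC",
  "GCCCAGCCTCAATCGAGTTCGCCAATGGAGGAGTACGGCCTGAAAGATAGACAGGTAGAGA",
  "CACGACCCCAAGCTCTGGGCGCCCACGAATGACTGGGA",
  strrep("N", 9), "TAGCTCGCCTGTATG", strrep("N", 10),
  "GACAGAGAATATGTGTAGAGGC"
)

oracle_rc <- function(s) {
  if (nchar(s) == 0) return("")
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Brute-force best Hamming occurrence: every offset, N in pattern matches
# any, N in read mismatches; fewest mismatches then smallest offset.
oracle_best_match <- function(read, pattern, max_mm, min_start = 0) {
  L <- nchar(read); m <- nchar(pattern)
  if (L < min_start + m) return(NULL)
  pv <- strsplit(pattern, "")[[1]]
  best <- NULL
  for (s in min_start:(L - m)) {
    rv <- strsplit(substr(read, s + 1, s + m), "")[[1]]
    mm <- sum(rv != pv & pv != "N")
    if (mm <= max_mm && (is.null(best) || mm < best$mm)) {
      best <- list(pos = s, mm = mm)
      if (mm == 0) break
    }
  }
  best
}

# Brute-force whitelist correction.
oracle_correct <- function(raw, wl_barcodes) {
  if (raw %in% wl_barcodes) return(raw)
  d <- vapply(wl_barcodes, function(b) {
    sum(strsplit(raw, "")[[1]] != strsplit(b, "")[[1]])
  }, integer(1))
  hits <- wl_barcodes[d == 1]
  if (length(hits) == 1) hits else NA_character_
}

# Exhaustive two-sided permutation p for the rank-sum U statistic, via a
# bitmask sweep over all subsets (independent of the combn-based exact mode).
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  mu <- n1 * n2 / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  hits <- 0; total <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) != n1) next
    total <- total + 1
    u <- sum(r[sel]) - n1 * (n1 + 1) / 2
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1
  }
  hits / total
}

random_dna_vec <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Plant `pattern` into a random read of length L at a random offset >= min_at.
plant_read <- function(pattern, L, at) {
  bg <- random_dna_vec(1, L)
  paste0(substr(bg, 1, at), pattern,
         substr(bg, at + nchar(pattern) + 1, L))
}

# Full in-memory filter -> pair pipeline on a sim_run.
filter_pairs_sim <- function(sim, cfg = filter_config(),
                             target = nc886_target(), design = nc886_gsp()) {
  f1 <- filter_r1(sim$r1, target, cfg)
  f2 <- filter_r2(sim$r2, target, design, cfg)
  reconcile_pairs(f1$reads, f2$reads)
}

# Toy GEX matrix with exact per-cell totals / gene counts / mito percent.
# One mito gene "MT-1" plus `max(genes)` regular genes.
toy_qc_matrix <- function(totals, genes, mito_pct) {
  ng <- max(genes)
  rn <- c("MT-1", paste0("G", seq_len(ng)))
  m <- matrix(0, nrow = ng + 1, ncol = length(totals),
              dimnames = list(rn, paste0("cell", seq_along(totals))))
  for (i in seq_along(totals)) {
    mito <- round(totals[i] * mito_pct[i] / 100)
    rest <- totals[i] - mito
    k <- genes[i] - 1  # non-mito genes detected
    base <- rest %/% k
    extra <- rest %% k
    m["MT-1", i] <- mito
    m[1 + seq_len(k), i] <- base + c(rep(1, extra), rep(0, k - extra))
  }
  m
}
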