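test_that("find_best_match: containment, budgets, tie-breaking", {
  set.seed(7)
  read <- plant_read(gsp_anchor, 80, 30)
  hit <- find_best_match(read, gsp_anchor, 0)
  expect_identical(hit$mismatches, 0L)
  expect_identical(hit$position, 30L)

  # one substitution inside the planted pattern
  mut <- read
  substr(mut, 35, 35) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 35, 35))[1]
  expect_identical(find_best_match(mut, gsp_anchor, 1)$mismatches, 1L)
  expect_null(find_best_match(mut, gsp_anchor, 0))

  # pattern longer than read -> no hit, not an error; empty pattern rejected
  expect_null(find_best_match("ACGT", "ACGTACGT", 2))
  expect_error(find_best_match("ACGT", "", 1), "empty pattern")

  # N semantics: N in pattern matches anything, N in read mismatches
  expect_identical(find_best_match("AANAA", "AAAAA", 1)$mismatches, 1L)
  expect_identical(find_best_match("ACGTA", "ANGTA", 0)$mismatches, 0L)

  # forward preferred over revcomp at equal (mm, offset)
  pal_read <- "AATT"  # contains both ACGT? use explicit planted case
  r <- paste0("ACGT", "ACGT")
  h <- find_best_match(r, "ACGT", 0, both_orientations = TRUE)
  expect_identical(h$orientation, "forward")
  # revcomp-only hit is found
  h2 <- find_best_match(reverse_complement(gsp_anchor), gsp_anchor, 0,
                        both_orientations = TRUE)
  expect_identical(h2$orientation, "revcomp")
})

test_that("find_best_match agrees with the brute-force oracle", {
  set.seed(123)
  n_bad <- 0
  for (i in 1:2000) {
    L <- sample(20:60, 1)
    m <- sample(4:12, 1)
    read <- random_dna_vec(1, L)
    if (runif(1) < 0.5) {
      pat <- random_dna_vec(1, m)
    } else {
      at <- sample(0:(L - m), 1)
      pat <- substr(read, at + 1, at + m)
      nerr <- sample(0:2, 1)
      if (nerr > 0) for (p in sample(m, nerr)) {
        substr(pat, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(pat, p, p)), 1)
      }
    }
    budget <- sample(0:2, 1)
    got <- find_best_match(read, pat, budget)
    want <- oracle_best_match(read, pat, budget)
    ok <- (is.null(got) && is.null(want)) ||
      (!is.null(got) && !is.null(want) &&
         got$position == want$pos && got$mismatches == want$mm)
    if (!ok) n_bad <- n_bad + 1
  }
  expect_identical(n_bad, 0)
})

test_that("filter_r1 selects true captures and skips short reads", {
  set.seed(5)
  tg <- nc886_target()
  cfg <- filter_config(max_mismatch = 1)
  prefix <- paste0(random_dna_vec(1, 26), "TTTCTTATATGGG")  # CB+UMI+TSO
  true_r1 <- vapply(1:10, function(i) {
    paste0(random_dna_vec(1, 26), "TTTCTTATATGGG",
           substr(tg$sequence, 1, 61))
  }, "")
  junk_r1 <- random_dna_vec(5, 100)
  short <- substr(true_r1[1], 1, 50)
  reads <- data.frame(
    read_id = sprintf("r%02d", 1:16),
    seq = c(true_r1, junk_r1, short),
    qual = strrep("I", nchar(c(true_r1, junk_r1, short))))
  out <- filter_r1(reads, tg, cfg)
  expect_identical(out$summary$n_pass, 10L)
  expect_identical(out$summary$n_skipped_short, 1L)
  expect_identical(out$reads$read_id, sprintf("r%02d", 1:10))
  expect_true(all(out$reads$pos == 39))
})

test_that("filter_r2 requires feature barcode AND target", {
  set.seed(6)
  tg <- nc886_target(); d <- nc886_gsp()
  cfg <- filter_config(max_mismatch = 1)
  anti <- reverse_complement(substr(tg$sequence, 1, 99))  # antisense capture
  mk <- function(insert) {
    paste0(random_dna_vec(1, 10), d$feature_barcode, random_dna_vec(1, 9),
           substr(insert, 1, 66))
  }
  both <- vapply(1:6, function(i) mk(anti), "")
  fb_only <- vapply(1:4, function(i) mk(random_dna_vec(1, 99)), "")
  tg_only <- vapply(1:3, function(i) {
    paste0(random_dna_vec(1, 34), substr(anti, 1, 66))
  }, "")
  reads <- data.frame(read_id = sprintf("x%02d", 1:13),
                      seq = c(both, fb_only, tg_only),
                      qual = strrep("I", 100))
  out <- filter_r2(reads, tg, d, cfg)
  expect_identical(out$summary$n_pass, 6L)
  expect_identical(sort(out$reads$read_id), sprintf("x%02d", 1:6))
  expect_identical(out$summary$n_pass_barcode_only, 4L)
  expect_true(all(out$reads$tg_orientation == "revcomp"))
})

test_that("pass sets are monotone in the mismatch budget", {
  set.seed(77)
  sim <- simulate_run(sim_config(n_cells_per_population = 10,
                                 nonspecific_fraction = 0.6,
                                 error_rate = 0.02, seed = 77))
  tg <- nc886_target(); d <- nc886_gsp()
  prev1 <- prev2 <- character(0)
  for (m in 0:3) {
    cfg <- filter_config(max_mismatch = m)
    p1 <- filter_r1(sim$r1, tg, cfg)$reads$read_id
    p2 <- filter_r2(sim$r2, tg, d, cfg)$reads$read_id
    expect_true(all(prev1 %in% p1))
    expect_true(all(prev2 %in% p2))
    prev1 <- p1; prev2 <- p2
  }
})

test_that("reconcile_pairs: intersection, order, soundness, duplicates", {
  mk <- function(ids) data.frame(read_id = ids,
                                 seq = strrep("A", 5), qual = strrep("I", 5))
  out <- reconcile_pairs(mk(c("a", "b", "c")), mk(c("b", "c", "d")))
  expect_identical(out$read_id, c("b", "c"))
  expect_identical(nrow(reconcile_pairs(mk(c("a")), mk(c("z")))), 0L)
  expect_error(reconcile_pairs(mk(c("a", "a")), mk("a")), "duplicate")
  expect_error(reconcile_pairs(mk("a"), mk(c("a", "a"))), "duplicate")

  # ground-truth bookkeeping: R1 passes a superset of R2
  r1 <- mk(c("a", "b", "c", "d"))
  r2 <- mk(c("b", "d"))
  expect_identical(nrow(reconcile_pairs(r1, r2)), 2L)
})

test_that("FASTQ IO round-trips and read IDs are normalized", {
  expect_identical(normalize_read_id(c("id1/1", "id2 2:N:0", "id3")),
                   c("id1", "id2", "id3"))
  reads <- data.frame(read_id = c("a", "b"),
                      seq = c("ACGTN", "GGGCC"),
                      qual = c("IIIII", "FFFFF"))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back, reads)
  # gz transparency
  fqz <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fqz)
  expect_identical(read_fastq(fqz), reads)
})

test_that("filtering is deterministic: byte-identical outputs", {
  sim <- simulate_run(sim_config(n_cells_per_population = 4,
                                 nonspecific_fraction = 0.5, seed = 3))
  dir <- tempfile(); dir.create(dir)
  write_fastq(sim$r1, file.path(dir, "R1.fastq"))
  write_fastq(sim$r2, file.path(dir, "R2.fastq"))
  p1 <- file.path(dir, "runA"); p2 <- file.path(dir, "runB")
  for (p in c(p1, p2)) {
    filter_pairs(file.path(dir, "R1.fastq"), file.path(dir, "R2.fastq"),
                 nc886_target(), nc886_gsp(), filter_config(),
                 out_prefix = p)
  }
  for (suf in c("_R1.fastq", "_R2.fastq")) {
    expect_identical(unname(tools::md5sum(paste0(p1, suf))),
                     unname(tools::md5sum(paste0(p2, suf))))
  }
})
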