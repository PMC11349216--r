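test_that("extract_cell_umi splits barcode and UMI, guards length", {
  an <- read_anatomy()
  seqs <- c(paste0(strrep("A", 16), strrep("C", 10), strrep("G", 74)),
            strrep("A", 25))
  out <- extract_cell_umi(seqs, an)
  expect_identical(out$cell_barcode, c(strrep("A", 16), NA))
  expect_identical(out$umi, c(strrep("C", 10), NA))
})

test_that("correct_barcode matches brute-force over random whitelists", {
  set.seed(21)
  wl <- whitelist(unique(random_dna_vec(60, 8)))
  # exact member
  expect_identical(correct_barcode(wl$barcodes[3], wl), wl$barcodes[3])
  # distance-1 unique
  bc <- wl$barcodes[1]
  # property sweep vs oracle (covers unique-d1, ambiguous, d>=2)
  raws <- c(random_dna_vec(120, 8), vapply(sample(wl$barcodes, 30, TRUE),
    function(b) { p <- sample(8, 1)
      substr(b, p, p) <- sample(setdiff(c("A","C","G","T"),
                                        substr(b, p, p)), 1); b }, ""))
  got <- correct_barcode(raws, wl)
  want <- vapply(raws, oracle_correct, "", wl_barcodes = wl$barcodes,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
  # explicit ambiguity: two members at distance 1
  wl2 <- whitelist(c("AAAA", "AAAT", "GGGG"))
  expect_identical(correct_barcode("AAAG", wl2), NA_character_)
  expect_error(correct_barcode("AAA", wl2), "length")
})

test_that("count_features dedups UMIs and stratifies by min mismatch", {
  an <- read_anatomy()
  cb <- strrep("A", 16)
  wl <- whitelist(cb)
  r1 <- function(umi) paste0(cb, umi, strrep("G", 74))
  u1 <- strrep("C", 10); u2 <- strrep("T", 10)
  # 3 reads sharing one UMI, all perfect -> 1 at every budget
  pairs <- data.frame(seq1 = rep(r1(u1), 3), tg_mm = c(0L, 0L, 0L))
  fc <- count_features(pairs, an, wl, max_budget = 2)
  expect_identical(unname(fc$counts[, cb]), c(1L, 1L, 1L))
  # u1 pm + u2 mm1 -> budget0 = 1, budget1 = 2
  pairs2 <- data.frame(seq1 = c(r1(u1), r1(u2)), tg_mm = c(0L, 1L))
  fc2 <- count_features(pairs2, an, wl, max_budget = 2)
  expect_identical(unname(fc2$counts[, cb]), c(1L, 2L, 2L))
  # min-mismatch rule: same UMI seen at mm 2 then mm 0 counts as pm
  pairs3 <- data.frame(seq1 = rep(r1(u1), 2), tg_mm = c(2L, 0L))
  fc3 <- count_features(pairs3, an, wl, max_budget = 2)
  expect_identical(unname(fc3$counts[, cb]), c(1L, 1L, 1L))
  expect_identical(rownames(fc3$counts),
                   c("target_pm", "target_mm1", "target_mm2"))
})

test_that("directional UMI collapse absorbs 1-off error UMIs", {
  an <- read_anatomy()
  cb <- strrep("A", 16)
  wl <- whitelist(cb)
  u <- strrep("C", 10)
  u_err <- paste0("T", strrep("C", 9))       # 1 substitution, 1 read
  u_real <- paste0(strrep("G", 5), strrep("C", 5))  # distance > 1
  r1 <- function(umi) paste0(cb, umi, strrep("G", 74))
  pairs <- data.frame(seq1 = c(rep(r1(u), 3), r1(u_err), rep(r1(u_real), 2)),
                      tg_mm = c(0L, 0L, 0L, 1L, 0L, 0L))
  exact <- count_features(pairs, an, wl, max_budget = 1)
  expect_identical(unname(exact$counts[, cb]), c(2L, 3L))
  dir_ <- count_features(pairs, an, wl, max_budget = 1,
                         umi_collapse = "directional")
  # u_err absorbed into u (3 >= 2*1-1); u keeps stratum pm
  expect_identical(unname(dir_$counts[, cb]), c(2L, 2L))
})

test_that("count_features: dedup idempotence, conservation, monotonicity", {
  sim <- simulate_run(sim_config(n_cells_per_population = 8,
                                 nonspecific_fraction = 0.5,
                                 error_rate = 0.01, seed = 9))
  res <- filter_pairs_sim(sim)
  fc <- count_features(res, wl = sim$whitelist)
  # conservation: reads in = counted + discarded + skipped
  s <- fc$summary
  expect_identical(s$n_reads_in,
                   s$n_reads_counted + s$n_reads_discarded_barcode +
                     s$n_reads_skipped_short)
  # budget monotonicity per cell
  expect_true(all(apply(fc$counts, 2, function(x) all(diff(x) >= 0))))
  # duplicating every read changes nothing
  fc2 <- count_features(rbind(res, res), wl = sim$whitelist)
  expect_identical(fc$counts, fc2$counts)
})

test_that("feature-count MTX round-trips; malformed inputs error", {
  sim <- simulate_run(sim_config(n_cells_per_population = 5,
                                 nonspecific_fraction = 0.3, seed = 13))
  fc <- count_features(filter_pairs_sim(sim), wl = sim$whitelist,
                       feature_name = "nc886")
  dir <- tempfile()
  write_feature_counts(fc, dir)
  back <- read_feature_counts(dir, feature_name = "nc886")
  expect_identical(back$counts, fc$counts)
  expect_identical(back$cells, fc$cells)

  # empty matrix is valid MTX with 0 entries
  fc0 <- count_features(data.frame(seq1 = character(), tg_mm = integer()),
                        wl = sim$whitelist)
  d0 <- tempfile()
  write_feature_counts(fc0, d0)
  expect_true(all(read_feature_counts(d0)$counts == 0))

  # dimension mismatch with sidecars -> error
  bad <- tempfile(); dir.create(bad)
  file.copy(file.path(dir, "matrix.mtx"), file.path(bad, "matrix.mtx"))
  writeLines(fc$cells[-1], file.path(bad, "barcodes.tsv"))
  writeLines(rownames(fc$counts), file.path(bad, "features.tsv"))
  expect_error(read_feature_counts(bad), "barcodes.tsv")
  # malformed header
  mm <- file.path(bad, "matrix.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general", "oops"), mm)
  writeLines(fc$cells, file.path(bad, "barcodes.tsv"))
  expect_error(read_feature_counts(bad), "malformed|scan")
})

test_that("merge_with_gex aligns barcodes and preserves GEX entries", {
  sim <- simulate_run(sim_config(n_cells_per_population = 5,
                                 nonspecific_fraction = 0.3, seed = 14))
  fc <- count_features(filter_pairs_sim(sim), wl = sim$whitelist,
                       feature_name = "nc886")
  gex <- simulate_gex(sim$whitelist$barcodes, n_genes = 30, seed = 2)
  merged <- merge_with_gex(gex, fc, budget = 1)
  expect_identical(dim(merged), c(31L, ncol(gex)))
  expect_identical(rownames(merged)[31], "nc886")
  expect_equal(as.matrix(merged[1:30, ]), as.matrix(gex))
  expect_equal(unname(as.numeric(merged["nc886", fc$cells])),
               unname(as.numeric(fc$counts[2, ])))
  # gex cells beyond fc get 0
  gex2 <- simulate_gex(c(sim$whitelist$barcodes, strrep("A", 16)),
                       n_genes = 10, seed = 3)
  merged2 <- merge_with_gex(gex2, fc)
  expect_identical(as.numeric(merged2["nc886", strrep("A", 16)]), 0)
  # disjoint barcodes -> hard error
  gex3 <- simulate_gex(paste0(strrep("A", 15), c("C", "G")), n_genes = 5, n_mito = 1)
  expect_error(merge_with_gex(gex3, fc), "overlap")
})
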