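#' Simulation configuration
#'
#' The generator emulates the validation experiment the capture method was
#' developed on: three cell populations with high, low and zero target
#' expression (high/low/zero emulating WPMY-1 / Hep3B-886 / HEK293T), a
#' dominant non-specific-priming read class (99 percent of oligo-tag reads
#' by default), PCR duplication and i.i.d. per-base substitution errors, on
#' 100-bp paired-end reads.
#'
#' @param n_cells_per_population cells in each of the three populations.
#' @param population_means expected true target molecules per cell,
#'   \code{c(high, low, zero)}; the zero entry must be 0. The 20/4/0
#'   defaults are desk-scale emulation constants, not measured values.
#' @param nonspecific_fraction fraction of oligo-tag read pairs whose insert
#'   is random non-target sequence (feature barcode retained).
#' @param reads_per_molecule mean reads per true molecule (shifted Poisson:
#'   1 + Poisson(mean-1)).
#' @param error_rate per-base substitution probability.
#' @param read_len read length in nt.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_cells_per_population = 50L,
                       population_means = c(high = 20, low = 4, zero = 0),
                       nonspecific_fraction = 0.99,
                       reads_per_molecule = 2,
                       error_rate = 0.005,
                       read_len = 100L,
                       seed = 1L) {
  stopifnot(n_cells_per_population >= 1L,
            length(population_means) == 3L,
            all(population_means >= 0),
            nonspecific_fraction >= 0, nonspecific_fraction <= 1,
            reads_per_molecule >= 1,
            error_rate >= 0, error_rate <= 1)
  if (population_means[3L] != 0) {
    stop("the zero population mean must be 0")
  }
  structure(list(n_cells_per_population = as.integer(n_cells_per_population),
                 population_means = setNames(as.numeric(population_means),
                                             c("high", "low", "zero")),
                 nonspecific_fraction = nonspecific_fraction,
                 reads_per_molecule = reads_per_molecule,
                 error_rate = error_rate,
                 read_len = as.integer(read_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Apply i.i.d. substitution errors to a character vector of reads.
apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      orig <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, orig), 1L)
    }
  }
  seqs
}

#' Simulate an oligo-tagged paired-end run with ground truth
#'
#' True-capture pairs follow the library anatomy: R1 = cell barcode + UMI +
#' TSO + sense target prefix; R2 = the bottom strand read from the Read2
#' adaptor, i.e. spacer1 + feature barcode + spacer2 + antisense target
#' (anchor first). Non-specific pairs keep the identical oligo payload but
#' carry a random insert in place of the target. Per-cell true molecule
#' counts are Poisson at the population mean; duplicates per molecule are
#' shifted Poisson; substitution errors are i.i.d. per base. Spacer bases
#' (N positions of the design) are instantiated randomly once per molecule.
#'
#' @param cfg a \code{sim_config}.
#' @param design a \code{gsp_design} (default the published design).
#' @param target a \code{target_gene} (default nc886).
#' @param anatomy a \code{read_anatomy}.
#' @return list of class \code{sim_run} with \code{r1}, \code{r2} (read
#'   tables as from \code{\link{read_fastq}}), \code{truth} (list with
#'   per-cell \code{cells} and per-read \code{reads} data.frames),
#'   \code{whitelist} (a \code{\link{whitelist}} of the planted barcodes)
#'   and \code{config}.
#' @export
simulate_run <- function(cfg = sim_config(), design = nc886_gsp(),
                         target = nc886_target(), anatomy = read_anatomy()) {
  prefix_len <- anatomy$cell_barcode_len + anatomy$umi_len + nchar(anatomy$tso)
  if (cfg$read_len < prefix_len + 1L) {
    stop(sprintf("read_len %d too short for cell barcode + UMI + TSO (%d nt)",
                 cfg$read_len, prefix_len))
  }
  set.seed(cfg$seed)
  n_pop <- cfg$n_cells_per_population
  n_cells <- 3L * n_pop
  pop <- rep(c("high", "low", "zero"), each = n_pop)

  # unique cell barcodes
  repeat {
    bcs <- random_dna(n_cells, anatomy$cell_barcode_len)
    if (!anyDuplicated(bcs)) break
  }

  anchor_end <- design$anchor_interval[2L]
  sense_core <- substr0(target$sequence, 0L, anchor_end)  # captured segment
  insert_len <- nchar(sense_core)

  n_mol_true <- stats::rpois(n_cells, cfg$population_means[pop])
  cell_of_mol <- rep.int(seq_len(n_cells), n_mol_true)
  n_true <- length(cell_of_mol)

  dup_true <- 1L + stats::rpois(n_true, cfg$reads_per_molecule - 1)
  t_reads <- sum(dup_true)
  f <- cfg$nonspecific_fraction
  n_ns <- if (f >= 1) stop("nonspecific_fraction must be < 1 for simulation")
          else as.integer(round(t_reads * f / (1 - f)))

  mol <- data.frame(
    cell = c(cell_of_mol,
             if (n_ns) sample.int(n_cells, n_ns, replace = TRUE)),
    class = rep(c("true_capture", "nonspecific"), c(n_true, n_ns)),
    dups = c(dup_true, rep(1L, n_ns)),
    stringsAsFactors = FALSE
  )
  n_mol <- nrow(mol)
  mol$umi <- random_dna(n_mol, anatomy$umi_len)
  mol$sp1 <- random_dna(n_mol, design$spacer1_len)
  mol$sp2 <- random_dna(n_mol, design$spacer2_len)
  mol$insert <- sense_core
  if (n_ns) {
    mol$insert[mol$class == "nonspecific"] <- random_dna(n_ns, insert_len)
  }

  ridx <- rep.int(seq_len(n_mol), mol$dups)
  n_reads <- length(ridx)
  r1 <- paste0(bcs[mol$cell[ridx]], mol$umi[ridx], anatomy$tso,
               mol$insert[ridx])
  r1 <- substr(r1, 1L, cfg$read_len)
  r2 <- paste0(mol$sp1[ridx], design$feature_barcode, mol$sp2[ridx],
               reverse_complement(mol$insert)[ridx])
  r2 <- substr(r2, 1L, cfg$read_len)
  r1 <- apply_errors(r1, cfg$error_rate)
  r2 <- apply_errors(r2, cfg$error_rate)
  ids <- sprintf("sim:%07d", seq_len(n_reads))
  qual1 <- strrep("I", nchar(r1))
  qual2 <- strrep("I", nchar(r2))

  truth_cells <- data.frame(
    cell_barcode = bcs, population = pop,
    true_molecules = as.integer(n_mol_true),
    stringsAsFactors = FALSE
  )
  # by construction each true molecule has a distinct random UMI; count
  # distinct (cell, umi) pairs so UMI collisions are reflected in the truth
  if (n_true) {
    key <- unique(paste(mol$cell[mol$class == "true_capture"],
                        mol$umi[mol$class == "true_capture"]))
    cnt <- table(sub(" .*$", "", key))
    truth_cells$true_molecules <- 0L
    truth_cells$true_molecules[as.integer(names(cnt))] <- as.integer(cnt)
  }
  truth_reads <- data.frame(
    read_id = ids, class = mol$class[ridx],
    cell_barcode = bcs[mol$cell[ridx]], umi = mol$umi[ridx],
    stringsAsFactors = FALSE
  )

  structure(list(
    r1 = data.frame(read_id = ids, seq = r1, qual = qual1,
                    stringsAsFactors = FALSE),
    r2 = data.frame(read_id = ids, seq = r2, qual = qual2,
                    stringsAsFactors = FALSE),
    truth = list(cells = truth_cells, reads = truth_reads),
    whitelist = whitelist(bcs),
    config = cfg
  ), class = "sim_run")
}

#' Write a simulated run to disk
#'
#' @param sim a \code{sim_run}.
#' @param dir output directory: \code{R1.fastq.gz}, \code{R2.fastq.gz},
#'   \code{whitelist.txt}, \code{truth_cells.tsv}, \code{truth_reads.tsv}.
#' @return \code{dir}, invisibly.
#' @export
write_sim_run <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$r1, file.path(dir, "R1.fastq.gz"))
  write_fastq(sim$r2, file.path(dir, "R2.fastq.gz"))
  writeLines(sim$whitelist$barcodes, file.path(dir, "whitelist.txt"))
  write.table(sim$truth$cells, file.path(dir, "truth_cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$reads, file.path(dir, "truth_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Compare recovered counts with simulation ground truth
#'
#' @param truth the \code{truth} element of a \code{sim_run}.
#' @param fc a \code{feature_counts} over the same barcodes.
#' @param budget mismatch budget to evaluate.
#' @return list with \code{per_population} (mean recovered and true counts),
#'   \code{spearman} (correlation of recovered vs true over all cells),
#'   \code{mean_abs_error}, \code{zero_pop_mean},
#'   \code{zero_pop_false_positives} (zero-population cells with any
#'   recovered count).
#' @export
evaluate_counts <- function(truth, fc, budget = 1L) {
  tc <- truth$cells
  idx <- match(tc$cell_barcode, fc$cells)
  if (anyNA(idx)) stop("truth barcodes missing from feature counts")
  rec <- as.numeric(fc$counts[budget + 1L, idx])
  per_pop <- do.call(rbind, lapply(split(seq_len(nrow(tc)), tc$population),
    function(i) data.frame(mean_recovered = mean(rec[i]),
                           mean_true = mean(tc$true_molecules[i]))))
  zero <- tc$population == "zero"
  rho <- if (stats::sd(rec) == 0 || stats::sd(tc$true_molecules) == 0) NA_real_
         else stats::cor(rec, tc$true_molecules, method = "spearman")
  list(per_population = per_pop,
       spearman = rho,
       mean_abs_error = mean(abs(rec - tc$true_molecules)),
       zero_pop_mean = mean(rec[zero]),
       zero_pop_false_positives = sum(rec[zero] > 0))
}

#' Simulate a small gene-expression matrix for integration tests
#'
#' Emits per-cell GEX counts only (whole-transcriptome content is out of
#' scope): Poisson counts over \code{n_genes} genes with lognormal library
#' sizes, the first \code{n_mito} genes named with the mitochondrial prefix.
#'
#' @param barcodes cell barcodes (column names).
#' @param n_genes,n_mito gene counts.
#' @param mean_libsize expected UMIs per cell.
#' @param mito_frac expected mitochondrial fraction.
#' @param seed RNG seed.
#' @return sparse genes x cells \code{dgCMatrix}.
#' @export
simulate_gex <- function(barcodes, n_genes = 100L, n_mito = 5L,
                         mean_libsize = 5000, mito_frac = 0.05, seed = 1L) {
  set.seed(seed)
  stopifnot(n_mito < n_genes)
  genes <- c(paste0("MT-G", seq_len(n_mito)),
             paste0("GENE", seq_len(n_genes - n_mito)))
  w <- c(rep(mito_frac / n_mito, n_mito),
         rep((1 - mito_frac) / (n_genes - n_mito), n_genes - n_mito))
  lib <- stats::rlnorm(length(barcodes), log(mean_libsize), 0.3)
  m <- matrix(stats::rpois(n_genes * length(barcodes),
                           outer(w, lib)), nrow = n_genes,
              dimnames = list(genes, barcodes))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}
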