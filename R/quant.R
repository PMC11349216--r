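#' Cell-barcode whitelist
#'
#' @param barcodes character vector of uniform-length barcodes; duplicates
#'   are an error.
#' @return object of class \code{whitelist}.
#' @export
whitelist <- function(barcodes) {
  barcodes <- as.character(barcodes)
  if (length(barcodes) == 0L) stop("empty whitelist")
  if (length(unique(nchar(barcodes))) != 1L) {
    stop("whitelist barcodes must all have the same length")
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in whitelist")
  structure(list(barcodes = barcodes, bc_len = nchar(barcodes[1L])),
            class = "whitelist")
}

#' @rdname whitelist
#' @param path plain-text file, one barcode per line.
#' @export
read_whitelist <- function(path) {
  whitelist(readLines(path, warn = FALSE))
}

#' Extract cell barcode and UMI from R1
#'
#' The first \code{cell_barcode_len} bases are the cell barcode; the next
#' \code{umi_len} are the UMI. Vectorised.
#'
#' @param seqs R1 sequences.
#' @param anatomy a \code{read_anatomy}.
#' @return data.frame with \code{cell_barcode}, \code{umi}; rows for reads
#'   shorter than barcode+UMI hold NA (callers count and drop them).
#' @export
extract_cell_umi <- function(seqs, anatomy = read_anatomy()) {
  need <- anatomy$cell_barcode_len + anatomy$umi_len
  ok <- nchar(seqs) >= need
  cb <- ifelse(ok, substr(seqs, 1L, anatomy$cell_barcode_len), NA_character_)
  umi <- ifelse(ok, substr(seqs, anatomy$cell_barcode_len + 1L, need),
                NA_character_)
  data.frame(cell_barcode = cb, umi = umi, stringsAsFactors = FALSE)
}

#' Correct raw cell barcodes against a whitelist
#'
#' Exact members map to themselves; a barcode at Hamming distance 1 from
#' exactly one whitelist member is corrected to it; anything else returns NA
#' (discard). 10x-style single-substitution rescue.
#'
#' @param raw character vector of observed barcodes (must match whitelist
#'   length).
#' @param wl a \code{whitelist}.
#' @return character vector: corrected barcode or NA.
#' @export
correct_barcode <- function(raw, wl) {
  stopifnot(inherits(wl, "whitelist"))
  if (any(nchar(raw) != wl$bc_len, na.rm = TRUE)) {
    stop("raw barcode length differs from whitelist length")
  }
  out <- ifelse(raw %in% wl$barcodes, raw, NA_character_)
  todo <- which(is.na(out) & !is.na(raw))
  if (length(todo)) {
    wlset <- new.env(parent = emptyenv())
    for (b in wl$barcodes) assign(b, TRUE, envir = wlset)
    bases <- c("A", "C", "G", "T")
    fix1 <- function(bc) {
      hit <- NULL
      for (p in seq_len(wl$bc_len)) {
        orig <- substr(bc, p, p)
        for (b in bases) {
          if (b == orig) next
          cand <- bc
          substr(cand, p, p) <- b
          if (exists(cand, envir = wlset, inherits = FALSE)) {
            if (!is.null(hit)) return(NA_character_)  # ambiguous
            hit <- cand
          }
        }
      }
      if (is.null(hit)) NA_character_ else hit
    }
    uniq <- unique(raw[todo])
    fixed <- vapply(uniq, fix1, character(1L))
    out[todo] <- fixed[match(raw[todo], uniq)]
  }
  out
}

#' Count target UMIs per cell, stratified by mismatch budget
#'
#' Groups validated read pairs by (corrected cell barcode, UMI); the stratum
#' of a group is the minimum target mismatch count among its reads (best
#' evidence wins). For each budget m in 0..max_budget the count of a cell is
#' the number of distinct UMIs whose stratum is <= m, so counts are
#' cumulative and non-decreasing in m ("pm", "mm1", ... strata).
#'
#' @param pairs data.frame with columns \code{seq1} (R1 sequence) and
#'   \code{tg_mm} (target-hit mismatches from R2), e.g. the output of
#'   \code{\link{reconcile_pairs}}.
#' @param anatomy a \code{read_anatomy}.
#' @param wl a \code{whitelist}, or NULL for whitelist-free mode (every
#'   observed barcode is its own cell; test-only).
#' @param max_budget largest stratum (default 5).
#' @param feature_name label used for the stratum feature names.
#' @param umi_collapse \code{"exact"} (default: distinct UMI sequences are
#'   distinct molecules) or \code{"directional"}: within a cell, a UMI at
#'   Hamming distance 1 from a kept UMI with at least twice-minus-one its
#'   read count is absorbed into it (sequencing-error rescue).
#' @return object of class \code{feature_counts}: list with \code{cells}
#'   (ordered barcodes), \code{counts} (integer matrix, rows =
#'   \code{<name>_pm}, \code{<name>_mm1}, ... = budgets 0..max_budget,
#'   columns = cells, cumulative), and \code{summary} (reads in / counted /
#'   discarded barcode / skipped short).
#' @export
count_features <- function(pairs, anatomy = read_anatomy(), wl = NULL,
                           max_budget = 5L, feature_name = "target",
                           umi_collapse = c("exact", "directional")) {
  umi_collapse <- match.arg(umi_collapse)
  stopifnot(max_budget >= 0L)
  n_in <- nrow(pairs)
  cu <- extract_cell_umi(pairs$seq1, anatomy)
  short <- is.na(cu$cell_barcode)
  mmv <- as.integer(pairs$tg_mm)
  if (is.null(wl)) {
    corrected <- cu$cell_barcode
  } else {
    corrected <- rep(NA_character_, n_in)
    corrected[!short] <- correct_barcode(cu$cell_barcode[!short], wl)
  }
  keep <- !short & !is.na(corrected)
  dt <- data.table::data.table(cell = corrected[keep], umi = cu$umi[keep],
                               mm = mmv[keep])
  grp <- if (nrow(dt)) dt[, list(mm = min(mm), n = .N), by = list(cell, umi)]
         else data.table::data.table(cell = character(), umi = character(),
                                     mm = integer(), n = integer())
  if (umi_collapse == "directional" && nrow(grp)) {
    grp <- collapse_umis_directional(grp)
  }
  cells <- if (is.null(wl)) sort(unique(grp$cell)) else wl$barcodes
  counts <- matrix(0L, nrow = max_budget + 1L, ncol = length(cells),
                   dimnames = list(stratum_names(feature_name, max_budget),
                                   cells))
  if (nrow(grp)) {
    ci <- match(grp$cell, cells)
    for (m in 0:max_budget) {
      tab <- tabulate(ci[grp$mm <= m], nbins = length(cells))
      counts[m + 1L, ] <- as.integer(tab)
    }
  }
  structure(list(
    cells = cells, counts = counts, max_budget = as.integer(max_budget),
    feature_name = feature_name,
    summary = list(n_reads_in = n_in,
                   n_reads_counted = sum(keep),
                   n_reads_discarded_barcode = sum(!short & is.na(corrected)),
                   n_reads_skipped_short = sum(short))
  ), class = "feature_counts")
}

# Directional UMI collapse within each cell (UMI-tools style): visit UMIs by
# descending read count; absorb a UMI into an already-kept neighbour at
# Hamming distance 1 whose count is >= 2 * count - 1. The kept UMI inherits
# the minimum mismatch stratum of everything it absorbs.
collapse_umis_directional <- function(grp) {
  bases <- c("A", "C", "G", "T")
  neighbours <- function(u) {
    out <- character(0)
    for (p in seq_len(nchar(u))) {
      for (b in bases) {
        if (b == substr(u, p, p)) next
        v <- u; substr(v, p, p) <- b
        out <- c(out, v)
      }
    }
    out
  }
  pieces <- lapply(split(grp, grp$cell), function(g) {
    g <- g[order(-g$n, g$umi), ]
    kept <- list()   # umi -> index into result rows
    res <- g[0, ]
    for (i in seq_len(nrow(g))) {
      u <- g$umi[i]
      parent <- NULL
      for (v in neighbours(u)) {
        j <- kept[[v]]
        if (!is.null(j) && res$n[j] >= 2L * g$n[i] - 1L) { parent <- j; break }
      }
      if (is.null(parent)) {
        res <- rbind(res, g[i, ])
        kept[[u]] <- nrow(res)
      } else {
        res$mm[parent] <- min(res$mm[parent], g$mm[i])
        res$n[parent] <- res$n[parent] + g$n[i]
      }
    }
    res
  })
  data.table::rbindlist(pieces)
}

stratum_names <- function(feature_name, max_budget) {
  c(paste0(feature_name, "_pm"),
    if (max_budget >= 1L) paste0(feature_name, "_mm", seq_len(max_budget)))
}

#' @export
print.feature_counts <- function(x, ...) {
  cat(sprintf("<feature_counts> %s: %d cells, budgets 0..%d\n",
              x$feature_name, length(x$cells), x$max_budget))
  cat("  total UMIs per budget:",
      paste(rowSums(x$counts), collapse = " "), "\n")
  invisible(x)
}

#' Write / read a feature-count matrix (MTX + sidecars)
#'
#' CellRanger-compatible layout: \code{matrix.mtx} (features x cells,
#' MatrixMarket triplet), \code{barcodes.tsv}, \code{features.tsv} (one row
#' per mismatch stratum). Round-trips losslessly.
#'
#' @param fc a \code{feature_counts}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_feature_counts <- function(fc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(fc$counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(fc$cells, file.path(dir, "barcodes.tsv"))
  writeLines(rownames(fc$counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname write_feature_counts
#' @param feature_name stratum label prefix expected in \code{features.tsv}.
#' @export
read_feature_counts <- function(dir, feature_name = "target") {
  m <- read_mtx_dir(dir)
  counts <- as.matrix(m)
  storage.mode(counts) <- "integer"
  structure(list(cells = colnames(counts), counts = counts,
                 max_budget = nrow(counts) - 1L,
                 feature_name = feature_name,
                 summary = NULL),
            class = "feature_counts")
}

# Shared MTX-directory reader with sidecar consistency checks.
read_mtx_dir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MTX ", mtx, ": ",
                                         conditionMessage(e)))
  feats <- readLines(file.path(dir, "features.tsv"), warn = FALSE)
  # tolerate CellRanger 3-column features.tsv
  feats <- vapply(strsplit(feats, "\t", fixed = TRUE), `[[`, "", 1L)
  bcs <- readLines(file.path(dir, "barcodes.tsv"), warn = FALSE)
  if (nrow(m) != length(feats)) {
    stop(sprintf("features.tsv has %d rows but matrix has %d",
                 length(feats), nrow(m)))
  }
  if (ncol(m) != length(bcs)) {
    stop(sprintf("barcodes.tsv has %d rows but matrix has %d columns",
                 length(bcs), ncol(m)))
  }
  dimnames(m) <- list(feats, bcs)
  m
}

#' Read / write a gene-expression matrix directory
#'
#' @param dir directory holding \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}.
#' @return sparse \code{dgCMatrix}, genes x cells, with dimnames.
#' @export
read_gex_mtx <- function(dir) {
  methods::as(read_mtx_dir(dir), "CsparseMatrix")
}

#' @rdname read_gex_mtx
#' @param gex genes x cells sparse or dense matrix with dimnames.
#' @export
write_gex_mtx <- function(gex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(gex, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(gex), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(gex), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Merge target counts into a gene-expression matrix
#'
#' Appends one feature row (the target at the chosen mismatch budget) to the
#' GEX matrix, aligned on cell barcodes. GEX cells absent from the feature
#' counts get 0; feature-count cells absent from the GEX are dropped. Zero
#' barcode overlap is a hard error (whitelist mismatch).
#'
#' @param gex genes x cells matrix (sparse ok) with barcode colnames.
#' @param fc a \code{feature_counts}.
#' @param budget mismatch budget of the appended row (default 1, the
#'   published choice).
#' @return matrix of the same class with one extra row named
#'   \code{<feature_name>} .
#' @export
merge_with_gex <- function(gex, fc, budget = 1L) {
  stopifnot(budget >= 0L, budget <= fc$max_budget)
  common <- intersect(colnames(gex), fc$cells)
  if (length(common) == 0L) {
    stop("no cell-barcode overlap between GEX and feature counts; ",
         "check the whitelist")
  }
  row <- setNames(numeric(ncol(gex)), colnames(gex))
  idx <- match(common, fc$cells)
  row[common] <- fc$counts[budget + 1L, idx]
  out <- rbind(gex, Matrix::Matrix(row, nrow = 1L, sparse = TRUE,
                                   dimnames = list(fc$feature_name, colnames(gex))))
  out
}
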