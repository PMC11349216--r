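#' Filtering configuration for oligo-tagged reads
#'
#' @param max_mismatch Hamming mismatch budget (substitutions only; the
#'   published pipeline settled on 1).
#' @param search_both_orientations search the reverse complement of each
#'   pattern as well (R2 carries the target antisense).
#' @param r1_insert_offset 0-based position where the insert starts in R1:
#'   cell barcode + UMI + TSO (16+10+13 = 39 by default).
#' @param r1_query_len length of the sense-strand target prefix searched in
#'   R1 (the published run used 100-bp reads against a 102-nt target, so a
#'   full-length query cannot fit; this is a knob, default 40).
#' @param r2_query_len length of the target query searched in R2, taken as
#'   the window ending at the anchor 3' end (default 40).
#' @param min_read_len reads shorter than this are skipped (counted, not
#'   errors).
#' @return object of class \code{filter_config}.
#' @export
filter_config <- function(max_mismatch = 1L,
                          search_both_orientations = TRUE,
                          r1_insert_offset = 39L,
                          r1_query_len = 40L,
                          r2_query_len = 40L,
                          min_read_len = 1L) {
  stopifnot(max_mismatch >= 0L, r1_insert_offset >= 0L,
            r1_query_len >= 1L, r2_query_len >= 1L)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 search_both_orientations = isTRUE(search_both_orientations),
                 r1_insert_offset = as.integer(r1_insert_offset),
                 r1_query_len = as.integer(r1_query_len),
                 r2_query_len = as.integer(r2_query_len),
                 min_read_len = as.integer(min_read_len)),
            class = "filter_config")
}

#' Best approximate occurrence of a pattern in a read
#'
#' Slides the pattern over every offset of the read (and over its reverse
#' complement when \code{both_orientations}), scoring Hamming distance.
#' Returns the hit with fewest mismatches within budget; ties broken by
#' smallest offset, then forward orientation. \code{N} in the pattern
#' matches any base; \code{N} in the read counts as a mismatch.
#'
#' @param read_seq the read sequence.
#' @param pattern the query (no shorter than 1 nt; longer than the read
#'   returns no hit).
#' @param max_mismatch mismatch budget.
#' @param both_orientations also search \code{reverse_complement(pattern)}.
#' @param min_start smallest 0-based offset considered.
#' @param pattern_name label recorded in the hit.
#' @return a list of class \code{match_hit} with \code{pattern_name},
#'   \code{position} (0-based), \code{mismatches}, \code{orientation}
#'   (\code{"forward"} or \code{"revcomp"}); or \code{NULL} if no offset
#'   qualifies.
#' @export
find_best_match <- function(read_seq, pattern, max_mismatch = 1L,
                            both_orientations = FALSE, min_start = 0L,
                            pattern_name = "pattern") {
  stopifnot(length(read_seq) == 1L, length(pattern) == 1L)
  if (!nzchar(pattern)) stop("empty pattern")
  fw <- hamming_scan(read_seq, pattern, max_mismatch, min_start)
  best <- NULL
  if (fw[1L, "pos"] >= 0L) {
    best <- list(pattern_name = pattern_name,
                 position = unname(fw[1L, "pos"]),
                 mismatches = unname(fw[1L, "mismatches"]),
                 orientation = "forward")
  }
  if (both_orientations) {
    rv <- hamming_scan(read_seq, reverse_complement(pattern),
                       max_mismatch, min_start)
    if (rv[1L, "pos"] >= 0L) {
      better <- is.null(best) ||
        rv[1L, "mismatches"] < best$mismatches ||
        (rv[1L, "mismatches"] == best$mismatches &&
           rv[1L, "pos"] < best$position)
      if (better) {
        best <- list(pattern_name = pattern_name,
                     position = unname(rv[1L, "pos"]),
                     mismatches = unname(rv[1L, "mismatches"]),
                     orientation = "revcomp")
      }
    }
  }
  if (!is.null(best)) class(best) <- "match_hit"
  best
}

# Vectorized two-orientation scan used by the filters. Returns a data.frame
# with pos / mm / orientation per read; pos -1 = miss, -2 = too short.
scan_both <- function(seqs, pattern, max_mismatch, both, min_start = 0L) {
  fw <- hamming_scan(seqs, pattern, max_mismatch, min_start)
  pos <- fw[, "pos"]; mm <- fw[, "mismatches"]
  ori <- rep("forward", length(seqs))
  if (both) {
    rv <- hamming_scan(seqs, reverse_complement(pattern),
                       max_mismatch, min_start)
    take <- rv[, "pos"] >= 0L &
      (pos < 0L | rv[, "mismatches"] < mm |
         (rv[, "mismatches"] == mm & rv[, "pos"] < pos))
    take[is.na(take)] <- FALSE
    pos[take] <- rv[take, "pos"]
    mm[take] <- rv[take, "mismatches"]
    ori[take] <- "revcomp"
    pos[pos == -2L & rv[, "pos"] == -2L] <- -2L
  }
  data.frame(pos = pos, mm = mm, orientation = ori,
             stringsAsFactors = FALSE)
}

# The R2 target query: window of the (sense) target ending at the anchor 3'
# end, so it always lies inside the captured segment.
r2_target_query <- function(target, design, len) {
  end <- design$anchor_interval[2L]
  start <- max(0L, end - len)
  substr0(target$sequence, start, end)
}

#' Filter R1 reads for the sense target prefix
#'
#' R1 of a true capture is cell barcode + UMI + TSO + sense target; the
#' filter searches the target 5' prefix (length \code{cfg$r1_query_len}) at
#' offsets at or beyond \code{cfg$r1_insert_offset}. Input order is
#' preserved. Reads too short to contain the query after the offset are
#' skipped and counted.
#'
#' @param reads data.frame from \code{\link{read_fastq}}.
#' @param target a \code{target_gene}.
#' @param cfg a \code{filter_config}.
#' @return list with \code{reads} (passing rows plus hit columns
#'   \code{pos}, \code{mm}, \code{orientation}) and \code{summary}
#'   (\code{n_in}, \code{n_pass}, \code{n_skipped_short}).
#' @export
filter_r1 <- function(reads, target, cfg = filter_config()) {
  query <- substr0(target$sequence, 0L,
                   min(cfg$r1_query_len, nchar(target$sequence)))
  hits <- scan_both(reads$seq, query, cfg$max_mismatch,
                    both = FALSE, min_start = cfg$r1_insert_offset)
  too_short <- nchar(reads$seq) < cfg$min_read_len
  skipped <- hits$pos == -2L | too_short
  pass <- hits$pos >= 0L & !too_short
  out <- cbind(reads[pass, , drop = FALSE], hits[pass, , drop = FALSE])
  rownames(out) <- NULL
  list(reads = out,
       summary = list(n_in = nrow(reads), n_pass = sum(pass),
                      n_skipped_short = sum(skipped)))
}

#' Filter R2 reads for feature barcode AND target sequence
#'
#' A read passes only if both the feature barcode and the target query are
#' found within the mismatch budget (both orientations searched by default;
#' R2 carries the antisense target and the sense feature barcode). This AND
#' is the non-specific-priming correction: reads primed on off-target RNA
#' carry the barcode but not the target.
#'
#' @param reads data.frame from \code{\link{read_fastq}}.
#' @param target a \code{target_gene}.
#' @param design a \code{gsp_design} (supplies the feature barcode and the
#'   anchor-adjacent target query window).
#' @param cfg a \code{filter_config}.
#' @return list with \code{reads} (passing rows plus columns \code{fb_pos},
#'   \code{fb_mm}, \code{fb_orientation}, \code{tg_pos}, \code{tg_mm},
#'   \code{tg_orientation}) and \code{summary}.
#' @export
filter_r2 <- function(reads, target, design, cfg = filter_config()) {
  tq <- r2_target_query(target, design, cfg$r2_query_len)
  fb <- scan_both(reads$seq, design$feature_barcode, cfg$max_mismatch,
                  both = cfg$search_both_orientations)
  tg <- scan_both(reads$seq, tq, cfg$max_mismatch,
                  both = cfg$search_both_orientations)
  too_short <- nchar(reads$seq) < cfg$min_read_len
  skipped <- fb$pos == -2L | tg$pos == -2L | too_short
  pass <- fb$pos >= 0L & tg$pos >= 0L & !too_short
  out <- reads[pass, , drop = FALSE]
  out$fb_pos <- fb$pos[pass]; out$fb_mm <- fb$mm[pass]
  out$fb_orientation <- fb$orientation[pass]
  out$tg_pos <- tg$pos[pass]; out$tg_mm <- tg$mm[pass]
  out$tg_orientation <- tg$orientation[pass]
  rownames(out) <- NULL
  list(reads = out,
       summary = list(n_in = nrow(reads), n_pass = sum(pass),
                      n_pass_barcode_only = sum(fb$pos >= 0L & tg$pos < 0L),
                      n_skipped_short = sum(skipped)))
}

#' Reconcile filtered R1/R2 by read ID
#'
#' Emits exactly the reads whose (normalized) ID passed both mate filters,
#' in R1 order, carrying both mates' sequence and quality. Duplicate IDs
#' within either mate table are a hard error (ambiguous pairing).
#'
#' @param r1_pass,r2_pass data.frames with at least \code{read_id},
#'   \code{seq}, \code{qual} (the outputs of \code{\link{filter_r1}} /
#'   \code{\link{filter_r2}}).
#' @return data.frame with \code{read_id}, \code{seq1}, \code{qual1},
#'   \code{seq2}, \code{qual2} plus any hit columns present in the inputs
#'   (R2 hit columns keep their names; R1 hit columns gain an \code{r1_}
#'   prefix).
#' @export
reconcile_pairs <- function(r1_pass, r2_pass) {
  if (anyDuplicated(r1_pass$read_id)) {
    stop("duplicate read ID in R1: ",
         r1_pass$read_id[duplicated(r1_pass$read_id)][1L])
  }
  if (anyDuplicated(r2_pass$read_id)) {
    stop("duplicate read ID in R2: ",
         r2_pass$read_id[duplicated(r2_pass$read_id)][1L])
  }
  keep <- r1_pass$read_id %in% r2_pass$read_id
  r1 <- r1_pass[keep, , drop = FALSE]
  idx <- match(r1$read_id, r2_pass$read_id)
  r2 <- r2_pass[idx, , drop = FALSE]
  out <- data.frame(read_id = r1$read_id,
                    seq1 = r1$seq, qual1 = r1$qual,
                    seq2 = r2$seq, qual2 = r2$qual,
                    stringsAsFactors = FALSE)
  extra1 <- setdiff(names(r1), c("read_id", "seq", "qual"))
  for (col in extra1) out[[paste0("r1_", col)]] <- r1[[col]]
  extra2 <- setdiff(names(r2), c("read_id", "seq", "qual"))
  for (col in extra2) out[[col]] <- r2[[col]]
  rownames(out) <- NULL
  out
}

#' Run the full pair filter on FASTQ files
#'
#' Convenience wrapper: read R1/R2, filter each mate, reconcile, optionally
#' write filtered FASTQs and a JSON summary.
#'
#' @param r1_path,r2_path input FASTQ(.gz).
#' @param target,design,cfg as in the single-mate filters.
#' @param out_prefix if non-NULL, writes \code{<prefix>_R1.fastq},
#'   \code{<prefix>_R2.fastq} and \code{<prefix>_summary.json}.
#' @return list with \code{pairs} (reconciled table) and \code{summary}.
#' @export
filter_pairs <- function(r1_path, r2_path, target, design,
                         cfg = filter_config(), out_prefix = NULL) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  f1 <- filter_r1(r1, target, cfg)
  f2 <- filter_r2(r2, target, design, cfg)
  pairs <- reconcile_pairs(f1$reads, f2$reads)
  summary <- list(r1 = f1$summary, r2 = f2$summary, n_paired = nrow(pairs))
  if (!is.null(out_prefix)) {
    write_fastq(data.frame(read_id = pairs$read_id, seq = pairs$seq1,
                           qual = pairs$qual1),
                paste0(out_prefix, "_R1.fastq"))
    write_fastq(data.frame(read_id = pairs$read_id, seq = pairs$seq2,
                           qual = pairs$qual2),
                paste0(out_prefix, "_R2.fastq"))
    jsonlite::write_json(summary, paste0(out_prefix, "_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(pairs = pairs, summary = summary)
}
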