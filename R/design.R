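#' Target gene for GSP capture
#'
#' A named reference sequence with optional masked intervals that a primer
#' anchor must avoid (the Pol III oligo-T terminator, intragenic box A/B
#' promoter elements). RNA input (\code{U}) is normalized to DNA (\code{T});
#' the sequence is stored uppercase, sense strand, 5'->3'. All coordinates in
#' the package are 0-based, half-open.
#'
#' @param name identifier for the target.
#' @param sequence DNA or RNA string over \code{A,C,G,T,U} (case-insensitive).
#' @param masked_intervals list of length-2 integer vectors \code{c(start,
#'   end)}, 0-based half-open, each within the sequence.
#' @return an object of class \code{target_gene} with fields \code{name},
#'   \code{sequence}, \code{masked_intervals}.
#' @examples
#' tg <- target_gene("toy", "ACGUACGUAA")
#' tg$sequence  # "ACGTACGTAA"
#' @export
target_gene <- function(name, sequence, masked_intervals = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  seq <- normalize_dna(sequence)
  if (!nzchar(seq)) stop("target sequence must be non-empty")
  len <- nchar(seq)
  for (iv in masked_intervals) {
    if (length(iv) != 2L || iv[1L] < 0L || iv[2L] > len || iv[2L] < iv[1L]) {
      stop(sprintf("masked interval [%s,%s) out of bounds for length-%d sequence",
                   iv[1L], iv[2L], len))
    }
  }
  structure(
    list(name = name, sequence = seq,
         masked_intervals = lapply(masked_intervals, as.integer)),
    class = "target_gene"
  )
}

#' @export
print.target_gene <- function(x, ...) {
  cat(sprintf("<target_gene> %s (%d nt)\n", x$name, nchar(x$sequence)))
  if (length(x$masked_intervals)) {
    ivs <- vapply(x$masked_intervals,
                  function(iv) sprintf("[%d,%d)", iv[1L], iv[2L]), "")
    cat("  masked:", paste(ivs, collapse = " "), "\n")
  }
  invisible(x)
}

#' Read anatomy of the 5' droplet library
#'
#' Fixed segment layout of the 10x Chromium 5' chemistry as it appears in the
#' feature library: Read 1 opens with a 16-nt cell barcode and 10-nt UMI
#' followed by the 13-nt template-switch oligo (TSO) sequence
#' \code{TTTCTTATATGGG}; the amplified cDNA is flanked by the Read 1 adapter
#' and, in the final library, partial P5/P7 sequences.
#'
#' @param cell_barcode_len,umi_len segment lengths in nt.
#' @param tso TSO sequence as read on the top strand.
#' @param read1_adapter Read 1 sequencing adapter (truseq-style).
#' @param library_p5_prefix,library_p7_suffix partial P5/P7 flanks added at
#'   library construction.
#' @return object of class \code{read_anatomy}.
#' @export
read_anatomy <- function(cell_barcode_len = 16L,
                         umi_len = 10L,
                         tso = "TTTCTTATATGGG",
                         read1_adapter = "CTACACGACGCTCTTCCGATCT",
                         library_p5_prefix = "ACACTCTTTCCC",
                         library_p7_suffix = "AGCCCACGAGAC") {
  stopifnot(cell_barcode_len > 0L, umi_len > 0L)
  tso <- normalize_dna(tso)
  if (!nzchar(tso)) stop("tso must be non-empty")
  for (f in list(read1_adapter, library_p5_prefix, library_p7_suffix)) {
    if (!nzchar(f)) stop("anatomy fields must be non-empty")
  }
  structure(
    list(cell_barcode_len = as.integer(cell_barcode_len),
         umi_len = as.integer(umi_len),
         tso = tso,
         read1_adapter = normalize_dna(read1_adapter),
         library_p5_prefix = normalize_dna(library_p5_prefix),
         library_p7_suffix = normalize_dna(library_p7_suffix)),
    class = "read_anatomy"
  )
}

# Internal validated constructor shared by parse_gsp / design_gsp.
new_gsp_design <- function(adaptor, spacer1_len, feature_barcode, spacer2_len,
                           target_anchor, anchor_interval, target = NULL) {
  d <- structure(
    list(adaptor = adaptor,
         spacer1_len = as.integer(spacer1_len),
         feature_barcode = feature_barcode,
         spacer2_len = as.integer(spacer2_len),
         target_anchor = target_anchor,
         anchor_interval = as.integer(anchor_interval)),
    class = "gsp_design"
  )
  if (!is.null(target)) validate_gsp(d, target)
  d
}

#' Full oligo sequence of a GSP design
#'
#' Concatenates adaptor, spacer1 (as \code{N}s), feature barcode, spacer2
#' (\code{N}s) and target anchor.
#'
#' @param design a \code{gsp_design}.
#' @return single character string.
#' @export
gsp_oligo <- function(design) {
  paste0(design$adaptor, strrep("N", design$spacer1_len),
         design$feature_barcode, strrep("N", design$spacer2_len),
         design$target_anchor)
}

#' Validate a GSP design against its target
#'
#' Checks that the reverse complement of the anchor equals the target window
#' at \code{anchor_interval} and that the interval avoids all masked
#' intervals.
#'
#' @param design a \code{gsp_design}.
#' @param target a \code{target_gene}.
#' @param check_mask also require the anchor window to avoid the target's
#'   masked intervals (designs parsed from a published oligo may legitimately
#'   overlap a mask).
#' @return the design, invisibly; errors on violation.
#' @export
validate_gsp <- function(design, target, check_mask = FALSE) {
  iv <- design$anchor_interval
  win <- substr0(target$sequence, iv[1L], iv[2L])
  if (!identical(reverse_complement(design$target_anchor), win)) {
    stop(sprintf("anchor does not reverse-complement target window [%d,%d)",
                 iv[1L], iv[2L]))
  }
  if (check_mask) {
    for (m in target$masked_intervals) {
      if (iv[1L] < m[2L] && m[1L] < iv[2L]) {
        stop(sprintf("anchor interval [%d,%d) intersects masked [%d,%d)",
                     iv[1L], iv[2L], m[1L], m[2L]))
      }
    }
  }
  invisible(design)
}

#' @export
print.gsp_design <- function(x, ...) {
  cat(sprintf("<gsp_design> %d/%d/%d/%d/%d nt (adaptor/spacer/barcode/spacer/anchor)\n",
              nchar(x$adaptor), x$spacer1_len, nchar(x$feature_barcode),
              x$spacer2_len, nchar(x$target_anchor)))
  cat("  oligo: 5'-", gsp_oligo(x), "-3'\n", sep = "")
  cat(sprintf("  anchor window: [%d,%d)\n",
              x$anchor_interval[1L], x$anchor_interval[2L]))
  invisible(x)
}

#' Parse a spike-in oligo into its five segments
#'
#' Locates the adaptor and feature barcode as exact literal substrings of the
#' oligo; the gaps between the located literals are the spacer lengths and
#' the suffix after spacer2 is the target anchor. The anchor interval is
#' resolved against \code{target} when supplied (the anchor must
#' reverse-complement a unique window of the target).
#'
#' @param oligo full oligo, 5'->3', with \code{N} wildcards in the spacers.
#' @param adaptor,feature_barcode literal segment sequences; each must occur
#'   exactly once in the oligo.
#' @param target optional \code{target_gene} used to locate the anchor.
#' @return a \code{gsp_design}.
#' @examples
#' d <- parse_gsp(gsp_oligo(nc886_gsp()), "CGGAGATGTGTATAAGAGACAG",
#'                "GTATGTCCGCTCGAT", nc886_target())
#' nchar(d$target_anchor)  # 20
#' @export
parse_gsp <- function(oligo, adaptor, feature_barcode, target = NULL) {
  oligo <- normalize_dna(oligo, allow_n = TRUE)
  adaptor <- normalize_dna(adaptor)
  feature_barcode <- normalize_dna(feature_barcode)
  locate1 <- function(lit, what) {
    hits <- gregexpr(lit, oligo, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) stop(sprintf("%s not found in oligo", what))
    if (length(hits) > 1L) stop(sprintf("%s occurs %d times in oligo (ambiguous)",
                                        what, length(hits)))
    as.integer(hits[1L]) - 1L  # 0-based
  }
  a0 <- locate1(adaptor, "adaptor")
  if (a0 != 0L) stop("adaptor is not a prefix of the oligo")
  b0 <- locate1(feature_barcode, "feature barcode")
  a_end <- nchar(adaptor)
  spacer1 <- b0 - a_end
  if (spacer1 < 0L) stop("feature barcode overlaps the adaptor")
  b_end <- b0 + nchar(feature_barcode)
  rest <- substr(oligo, b_end + 1L, nchar(oligo))
  # spacer2 = leading N run of the remainder; anchor = what follows
  sp2 <- regmatches(rest, regexpr("^N*", rest))
  spacer2 <- nchar(sp2)
  anchor <- substr(rest, spacer2 + 1L, nchar(rest))
  if (!nzchar(anchor)) stop("no target anchor after spacer2")
  if (grepl("N", anchor, fixed = TRUE)) {
    stop("target anchor contains N wildcards; segment boundaries ambiguous")
  }
  iv <- c(NA_integer_, NA_integer_)
  if (!is.null(target)) {
    win <- reverse_complement(anchor)
    hits <- gregexpr(win, target$sequence, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) stop("anchor does not reverse-complement any target window")
    if (length(hits) > 1L) stop("anchor matches multiple target windows")
    iv <- c(hits[1L] - 1L, hits[1L] - 1L + nchar(win))
  }
  new_gsp_design(adaptor, spacer1, feature_barcode, spacer2, anchor, iv,
                 target = target)
}

#' Mask the Pol III oligo-T terminator of a target
#'
#' Pol III transcripts end in a run of 4-6 thymidylates (the terminator,
#' transcribed as 3' oligo-U); a primer anchored there would prime on every
#' Pol III gene. Adds a masked interval covering the maximal 3'-terminal run
#' of \code{>= min_t_run} T's, if present. Box A / box B promoter masks are
#' appended by the caller as explicit intervals.
#'
#' @param target a \code{target_gene}.
#' @param min_t_run minimum run length to mask (default 4).
#' @return the target with the terminal interval appended to
#'   \code{masked_intervals} (unchanged if no qualifying run).
#' @export
mask_polIII_motifs <- function(target, min_t_run = 4L) {
  stopifnot(min_t_run >= 1L)
  s <- target$sequence
  len <- nchar(s)
  run <- attr(regexpr("T*$", s), "match.length")
  if (run >= min_t_run) {
    target$masked_intervals <- c(target$masked_intervals,
                                 list(c(len - run, len)))
  }
  target
}

#' Design a GSP anchored at the 3'-most unmasked target window
#'
#' Enumerates all windows of width \code{anchor_len}, rejects those
#' intersecting a masked interval, takes the 3'-most survivor and builds the
#' primer as \code{adaptor + N*spacer1 + feature_barcode + N*spacer2 +
#' reverse_complement(window)}.
#'
#' @param target a \code{target_gene} (mask it first; see
#'   \code{\link{mask_polIII_motifs}}).
#' @param anchor_len anchor width in nt (20 in the published design).
#' @param feature_barcode,adaptor literal payload segments.
#' @param spacer_lens integer pair \code{c(spacer1, spacer2)}.
#' @return a validated \code{gsp_design}.
#' @export
design_gsp <- function(target, anchor_len,
                       feature_barcode, adaptor,
                       spacer_lens = c(10L, 9L)) {
  len <- nchar(target$sequence)
  stopifnot(anchor_len >= 1L, anchor_len <= len, length(spacer_lens) == 2L)
  ok_start <- -1L
  for (s in seq(len - anchor_len, 0L)) {     # 3'-most first
    e <- s + anchor_len
    clash <- any(vapply(target$masked_intervals,
                        function(m) s < m[2L] && m[1L] < e, logical(1L)))
    if (!clash) { ok_start <- s; break }
  }
  if (ok_start < 0L) {
    ivs <- paste(vapply(target$masked_intervals,
                        function(m) sprintf("[%d,%d)", m[1L], m[2L]), ""),
                 collapse = " ")
    stop(sprintf("no unmasked window of width %d; masked: %s", anchor_len, ivs))
  }
  win <- substr0(target$sequence, ok_start, ok_start + anchor_len)
  d <- new_gsp_design(normalize_dna(adaptor), spacer_lens[1L],
                      normalize_dna(feature_barcode), spacer_lens[2L],
                      reverse_complement(win),
                      c(ok_start, ok_start + anchor_len))
  validate_gsp(d, target, check_mask = TRUE)
  d
}

#' Reconstruct the library intermediates of a GSP capture
#'
#' Builds the three templates the spike-in chemistry produces, all stored as
#' top strands 5'->3' with \code{N} wildcards at randomized positions
#' (spacers, cell barcode, UMI):
#' \describe{
#'   \item{first_strand_cdna}{GSP extension product: full oligo +
#'     reverse complement of the target upstream of the anchor + the
#'     non-templated \code{CCC} added at template switching.}
#'   \item{amplified_cdna_top}{Read1 adapter + N16 cell barcode + N10 UMI +
#'     TSO + sense target up to the anchor end + spacer2 + RC(feature
#'     barcode) + spacer1 + RC(adaptor).}
#'   \item{library_top}{amplified cDNA flanked by partial P5/P7.}
#' }
#'
#' @param design a \code{gsp_design} with a resolved anchor interval.
#' @param target the \code{target_gene} the design was validated against.
#' @param anatomy a \code{read_anatomy}.
#' @param ccc_len length of the non-templated C tail (default 3).
#' @return object of class \code{template_set} with the three template
#'   strings.
#' @export
build_templates <- function(design, target, anatomy = read_anatomy(),
                            ccc_len = 3L) {
  validate_gsp(design, target)
  iv <- design$anchor_interval
  if (anyNA(iv)) stop("design has no resolved anchor interval")
  first_strand <- paste0(gsp_oligo(design),
                         reverse_complement(substr0(target$sequence, 0L, iv[1L])),
                         strrep("C", ccc_len))
  amplified <- paste0(anatomy$read1_adapter,
                      strrep("N", anatomy$cell_barcode_len),
                      strrep("N", anatomy$umi_len),
                      anatomy$tso,
                      substr0(target$sequence, 0L, iv[2L]),
                      strrep("N", design$spacer2_len),
                      reverse_complement(design$feature_barcode),
                      strrep("N", design$spacer1_len),
                      reverse_complement(design$adaptor))
  library_top <- paste0(anatomy$library_p5_prefix, amplified,
                        anatomy$library_p7_suffix)
  structure(list(first_strand_cdna = first_strand,
                 amplified_cdna_top = amplified,
                 library_top = library_top),
            class = "template_set")
}

#' Wildcard-aware string equality
#'
#' Position-by-position comparison where \code{N} on either side matches any
#' base; used to compare built templates with printed reference strands.
#'
#' @param a,b equal-length strings over \code{A,C,G,T,N}.
#' @return TRUE/FALSE.
#' @export
seq_equal_n <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (nchar(a) == 0L) return(TRUE)
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  all(av == bv | av == "N" | bv == "N")
}

# ---- canonical built-ins (the published nc886 design) ----------------------

#' The 102-nt nc886 reference target
#'
#' nc886 (vtRNA2-1) is a 102-nt RNA polymerase III transcript with no polyA
#' tail; the reference is stored U->T normalized. No intervals are masked by
#' default.
#'
#' @return a \code{target_gene}.
#' @export
nc886_target <- function() {
  target_gene(
    "nc886",
    paste0("CGGGUCGGAGUUAGCUCAAGCGGUUACCUCCUCAUGCCGGACUUUCUAUCUGUCCAUCUCU",
           "GUGCUGGGGUUCGAGACCCGCGGGUGCUUACUGACCCUUUU")
  )
}

#' The published nc886 gene-specific primer
#'
#' 76-mer spike-in oligo: 22-nt Read2N adaptor, 10-nt spacer, 15-nt feature
#' barcode, 9-nt spacer, 20-nt anchor reverse-complementary to the 3' end of
#' nc886 (window [79,99), which overlaps the terminal TTTT terminator by one
#' base -- the published placement).
#'
#' @return a \code{gsp_design} resolved against \code{\link{nc886_target}}.
#' @export
nc886_gsp <- function() {
  parse_gsp(
    paste0("CGGAGATGTGTATAAGAGACAG", strrep("N", 10L), "GTATGTCCGCTCGAT",
           strrep("N", 9L), "AGGGTCAGTAAGCACCCGCG"),
    adaptor = "CGGAGATGTGTATAAGAGACAG",
    feature_barcode = "GTATGTCCGCTCGAT",
    target = nc886_target()
  )
}

# ---- IO --------------------------------------------------------------------

#' Read a target sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @param name target name; defaults to the FASTA record name.
#' @return a \code{target_gene}.
#' @export
read_target_fasta <- function(path, name = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  target_gene(if (is.null(name)) names(ss)[1L] else name,
              as.character(ss[[1L]]))
}

#' Read a design configuration (JSON)
#'
#' Expected keys: \code{adaptor}, \code{feature_barcode}, \code{spacer_lens}
#' (length 2), \code{anchor_len}, optional \code{anatomy} overrides
#' (\code{cell_barcode_len}, \code{umi_len}, \code{tso}, ...).
#'
#' @param path JSON file.
#' @return list with elements \code{adaptor}, \code{feature_barcode},
#'   \code{spacer_lens}, \code{anchor_len}, \code{anatomy}.
#' @export
read_design_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("adaptor", "feature_barcode")) {
    if (is.null(cfg[[k]])) stop("design config missing field: ", k)
  }
  anatomy <- do.call(read_anatomy, as.list(cfg$anatomy %||% list()))
  list(adaptor = cfg$adaptor,
       feature_barcode = cfg$feature_barcode,
       spacer_lens = as.integer(cfg$spacer_lens %||% c(10L, 9L)),
       anchor_len = as.integer(cfg$anchor_len %||% 20L),
       anatomy = anatomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
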