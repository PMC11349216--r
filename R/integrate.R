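#' Cell-level QC thresholds
#'
#' The published criteria, implemented with the printed strict
#' inequalities: total UMI count > \code{min_umi_count}, detected genes >
#' \code{min_genes}, mitochondrial percentage < \code{max_mito_pct}.
#'
#' @param min_umi_count,min_genes,max_mito_pct thresholds (defaults 2000,
#'   200, 15).
#' @return object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(min_umi_count = 2000, min_genes = 200,
                          max_mito_pct = 15) {
  stopifnot(min_umi_count >= 0, min_genes >= 0,
            max_mito_pct >= 0, max_mito_pct <= 100)
  structure(list(min_umi_count = min_umi_count, min_genes = min_genes,
                 max_mito_pct = max_mito_pct),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' @param gex genes x cells matrix (sparse ok) with gene rownames.
#' @param thr a \code{qc_thresholds}.
#' @param mito_prefix prefix identifying mitochondrial genes (default
#'   \code{"MT-"}); if no feature matches, a warning is issued and the mito
#'   criterion passes vacuously.
#' @return list with \code{gex} (retained cells), \code{report}: per-cell
#'   metrics (\code{n_count}, \code{n_feature}, \code{pct_mito},
#'   \code{pass}) and per-criterion removal counts.
#' @export
qc_filter <- function(gex, thr = qc_thresholds(), mito_prefix = "MT-") {
  n_count <- Matrix::colSums(gex)
  n_feature <- Matrix::colSums(gex > 0)
  mito <- startsWith(rownames(gex), mito_prefix)
  if (!any(mito)) {
    warning("no features with prefix '", mito_prefix,
            "'; mitochondrial criterion passes vacuously")
    pct_mito <- rep(0, ncol(gex))
  } else {
    pct_mito <- 100 * Matrix::colSums(gex[mito, , drop = FALSE]) /
      pmax(n_count, 1)
  }
  pass_count <- n_count > thr$min_umi_count
  pass_genes <- n_feature > thr$min_genes
  pass_mito <- pct_mito < thr$max_mito_pct
  pass <- pass_count & pass_genes & pass_mito
  list(gex = gex[, pass, drop = FALSE],
       report = list(
         metrics = data.frame(cell = colnames(gex), n_count = n_count,
                              n_feature = n_feature, pct_mito = pct_mito,
                              pass = pass, row.names = NULL),
         removed_low_count = sum(!pass_count),
         removed_low_genes = sum(!pass_genes),
         removed_high_mito = sum(!pass_mito),
         n_in = ncol(gex), n_retained = sum(pass)))
}

#' Log-normalize and z-transform a count matrix
#'
#' Per cell: \code{log1p(count / cell_total * scale_factor)}; per feature:
#' center and scale across cells using the population (n) standard
#' deviation. Constant features get an all-zero row and are flagged.
#' Zero-total cells are excluded with a warning.
#'
#' @param gex genes x cells count matrix (sparse ok).
#' @param scale_factor per-cell normalization target (default 10000).
#' @return list with \code{normalized} (log-normalized matrix), \code{z}
#'   (dense z-score matrix), \code{constant_features} (character vector).
#' @export
lognorm_z <- function(gex, scale_factor = 1e4) {
  totals <- Matrix::colSums(gex)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-total cell(s) excluded")
    gex <- gex[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (ncol(gex) < 2L) stop("need at least 2 retained cells")
  norm <- log1p(t(t(as.matrix(gex)) / totals * scale_factor))
  mu <- rowMeans(norm)
  sdv <- sqrt(rowMeans((norm - mu)^2))   # population sd
  constant <- sdv == 0
  z <- (norm - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  list(normalized = norm, z = z,
       constant_features = rownames(gex)[constant])
}

#' Quantile grouping of a target expression vector
#'
#' Zero-inflation rule: all-zero cells go to bin 1; the non-zero cells are
#' then binned by the quantiles of their own distribution into bins
#' 1..n_bins, ties assigned to the lower bin.
#'
#' @param expr numeric per-cell expression (non-negative).
#' @param n_bins number of quantile bins (>= 2).
#' @return integer vector of bin labels in 1..n_bins.
#' @export
quantile_groups <- function(expr, n_bins = 4L) {
  stopifnot(n_bins >= 2L)
  labels <- rep(1L, length(expr))
  nz <- which(expr > 0)
  if (length(unique(expr)) <= 1L) {
    warning("all-equal expression; single bin")
    return(labels)
  }
  if (length(nz)) {
    br <- unique(stats::quantile(expr[nz], probs = seq(0, 1, 1 / n_bins),
                                 names = FALSE))
    if (length(br) < 2L) {
      labels[nz] <- 1L
    } else {
      # right-closed intervals: a value equal to a break falls in the lower bin
      labels[nz] <- as.integer(cut(expr[nz], breaks = br,
                                   include.lowest = TRUE, right = TRUE))
      # collapsed duplicate breaks can shrink the bin count; rescale to 1..k
    }
  }
  labels
}

#' Wilcoxon rank-sum comparison of two expression groups
#'
#' Two-sided rank-sum test. \code{exact = TRUE} enumerates all
#' \code{choose(n1+n2, n1)} group assignments and reports the permutation
#' p-value \code{P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|)}; the default
#' normal approximation applies the tie correction (no continuity
#' correction).
#'
#' @param group_a,group_b numeric vectors (each >= 3 values; degenerate
#'   input errors).
#' @param exact force exact enumeration (default: exact when both groups
#'   have <= 10 values).
#' @return list with \code{statistic} (U for group_a), \code{p_value},
#'   \code{method}.
#' @export
rank_sum_compare <- function(group_a, group_b, exact = NULL) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 3L || n2 < 3L) stop("each group needs >= 3 values")
  if (is.null(exact)) exact <- n1 <= 10L && n2 <= 10L
  x <- c(group_a, group_b)
  r <- rank(x)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (exact) {
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    ties <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) stop("degenerate ranks (all values tied)")
    p <- min(1, 2 * stats::pnorm(-abs(u - mu) / sqrt(sigma2)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = u, p_value = p, method = method)
}
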