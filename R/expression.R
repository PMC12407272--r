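#' Transcripts per million
#'
#' \code{tpm = (count / length_kb) / sum(count / length_kb) * 1e6} per
#' sample; every column sums to 1e6.
#'
#' @param counts Gene-by-sample integer matrix (gene rownames).
#' @param lengths Named effective lengths in bp (> 0), covering all genes.
#' @return Matrix of TPM values.
#' @export
compute_tpm <- function(counts, lengths) {
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  len <- lengths[rownames(counts)]
  if (any(is.na(len)) || any(len <= 0)) {
    stop("every gene needs a positive effective length")
  }
  rate <- counts / (len / 1000)
  cs <- colSums(rate)
  zero <- cs == 0
  if (any(zero)) {
    stop("all-zero sample: ", colnames(counts)[which(zero)[1]])
  }
  sweep(rate, 2, cs, "/") * 1e6
}

#' Expressed-gene filter
#'
#' Genes with TPM strictly above \code{threshold} in at least one sample.
#'
#' @param tpm TPM matrix.
#' @param threshold TPM threshold (strict >).
#' @param subgenome Optional named subgenome labels for the per-subgenome
#'   summary.
#' @return List with \code{genes} (character vector) and \code{summary}
#'   (per-subgenome expressed counts, if labels given).
#' @export
filter_expressed <- function(tpm, threshold = 0.1, subgenome = NULL) {
  keep <- rownames(tpm)[apply(tpm > threshold, 1, any)]
  summ <- NULL
  if (!is.null(subgenome)) {
    summ <- as.data.frame(table(subgenome = subgenome[keep]),
                          stringsAsFactors = FALSE)
    names(summ)[2] <- "expressed"
  }
  list(genes = keep, summary = summ)
}

#' Median-of-ratios size factors
#'
#' @param counts Gene-by-sample count matrix.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  gm <- rowMeans(lg)
  use <- is.finite(gm)
  if (!any(use)) stop("no gene with all-positive counts for size factors")
  sf <- apply(counts[use, , drop = FALSE], 2, function(k) {
    exp(stats::median(log(k) - gm[use], na.rm = TRUE))
  })
  sf
}

#' Negative-binomial Wald test for differential expression
#'
#' Median-of-ratios normalisation, per-gene method-of-moments dispersion
#' moderated toward the genome-wide median (floored at 1e-8), and a Wald
#' test on the log2 fold change with negative-binomial variance;
#' p-values use a t reference whose degrees of freedom add the
#' moderation prior to the residual df, and are BH-adjusted. The DEG
#' flag is |log2FC| > log2(de_fc) and adjusted p < de_fdr.
#'
#' @param counts Gene-by-sample matrix.
#' @param group_a,group_b Column names of the two conditions
#'   (log2FC is B over A so that a positive value means up in B).
#' @param sf Optional externally computed size factors, named by sample
#'   (e.g. library-level factors when rows are homoeolog pair halves).
#' @param de_fc,de_fdr DEG thresholds (fold change, FDR).
#' @return data.frame gene_id, base_mean, log2fc, se, stat, p, adj_p, deg;
#'   genes with zero counts in all samples are excluded (attribute
#'   \code{excluded}).
#' @export
nb_differential <- function(counts, group_a, group_b, sf = NULL,
                            de_fc = 2, de_fdr = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("at least 2 replicates per condition are required")
  }
  cols <- c(group_a, group_b)
  if (!all(cols %in% colnames(counts))) stop("unknown sample column")
  k <- counts[, cols, drop = FALSE]
  excluded <- rownames(k)[rowSums(k) == 0]
  k <- k[rowSums(k) > 0, , drop = FALSE]
  if (is.null(sf)) sf <- size_factors(k)
  else sf <- sf[cols]
  q <- sweep(k, 2, sf, "/")
  n1 <- length(group_a); n2 <- length(group_b)
  qa <- q[, group_a, drop = FALSE]; qb <- q[, group_b, drop = FALSE]
  ma <- rowMeans(qa); mb <- rowMeans(qb)
  va <- rowSums((qa - ma)^2) / (n1 - 1)
  vb <- rowSums((qb - mb)^2) / (n2 - 1)
  disp_of <- function(v, m) ifelse(m > 0, (v - m) / m^2, NA)
  alpha_g <- rowMeans(cbind(disp_of(va, ma), disp_of(vb, mb)), na.rm = TRUE)
  alpha_g[is.na(alpha_g)] <- 0
  # moderate the noisy per-gene estimate toward the genome-wide median
  # (few replicates give MoM little information per gene)
  prior_df <- 6
  resid_df <- n1 + n2 - 2
  alpha_med <- stats::median(pmax(alpha_g, 0))
  alpha <- pmax((prior_df * alpha_med + resid_df * alpha_g) /
                  (prior_df + resid_df), 1e-8)
  eps <- 0.5
  lfc <- log2((mb + eps) / (ma + eps))
  l2 <- log(2)^2
  var_log2 <- function(m, n) (m + eps + alpha * m^2) / n / ((m + eps)^2 * l2)
  se <- sqrt(var_log2(ma, n1) + var_log2(mb, n2))
  stat <- lfc / se
  p <- 2 * stats::pt(-abs(stat), df = prior_df + resid_df)
  adj <- bh_adjust(p)
  res <- data.frame(gene_id = rownames(k), base_mean = (ma + mb) / 2,
                    log2fc = lfc, se = se, stat = stat, p = p, adj_p = adj,
                    deg = abs(lfc) > log2(de_fc) & adj < de_fdr,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  attr(res, "size_factors") <- sf
  res
}

#' Homoeolog expression bias
#'
#' Within each tissue, tests each homoeolog pair's A member against its B
#' member across replicates using the negative-binomial Wald machinery
#' (log2FC is A over B). Size factors are the library-level factors of the
#' original samples, shared by the A and B halves of the same library.
#' Pairs are classed A-dominant / B-dominant at adjusted p below
#' \code{bias_adj_p}, else unbiased; the pooled call flags a pair biased
#' in at least one tissue (\code{pooling = "any"}) or in a majority of
#' tissues, with direction by the significance-weighted sign.
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Sample metadata (sample, tissue, condition, replicate);
#'   only condition "" or "CTL" samples are used.
#' @param map A \code{homoeolog_map} (or data.frame with gene_a, gene_b).
#' @param bias_adj_p Adjusted-p threshold.
#' @param pooling "any" or "majority".
#' @return List with \code{calls} (pair-level pooled calls), \code{per_tissue}
#'   (long table of per-tissue results) and \code{summary} (per-tissue and
#'   pooled class counts).
#' @export
homoeolog_bias <- function(counts, samples, map, bias_adj_p = 0.01,
                           pooling = c("any", "majority")) {
  pooling <- match.arg(pooling)
  pairs <- if (inherits(map, "homoeolog_map")) map$pairs else map
  use <- samples$condition %in% c("", "CTL")
  samples <- samples[use, ]
  lib_sf <- size_factors(counts[, samples$sample, drop = FALSE])
  ok <- pairs$gene_a %in% rownames(counts) & pairs$gene_b %in% rownames(counts)
  pairs <- pairs[ok, ]
  skipped <- 0L
  per_tissue <- list()
  for (tis in unique(samples$tissue)) {
    scols <- samples$sample[samples$tissue == tis]
    ka <- counts[pairs$gene_a, scols, drop = FALSE]
    kb <- counts[pairs$gene_b, scols, drop = FALSE]
    both_zero <- rowSums(ka) + rowSums(kb) == 0
    skipped <- skipped + sum(both_zero)
    pk <- cbind(ka, kb)
    colnames(pk) <- c(paste0(scols, ".A"), paste0(scols, ".B"))
    rownames(pk) <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
    sf <- stats::setNames(rep(lib_sf[scols], 2), colnames(pk))
    res <- nb_differential(pk[!both_zero, , drop = FALSE],
                           group_a = paste0(scols, ".B"),
                           group_b = paste0(scols, ".A"),
                           sf = sf)
    # log2fc is A over B by the group ordering above
    res$tissue <- tis
    res$class <- ifelse(res$adj_p < bias_adj_p,
                        ifelse(res$log2fc > 0, "A-dominant", "B-dominant"),
                        "unbiased")
    per_tissue[[tis]] <- res
  }
  pt <- do.call(rbind, per_tissue)
  rownames(pt) <- NULL

  sig <- pt[pt$class != "unbiased", ]
  n_tis <- length(unique(samples$tissue))
  agg_sig <- tapply(sig$tissue, sig$gene_id, length)
  dir_score <- tapply(sign(sig$log2fc), sig$gene_id, sum)
  all_ids <- unique(pt$gene_id)
  n_sig <- ifelse(all_ids %in% names(agg_sig), agg_sig[all_ids], 0)
  biased <- if (pooling == "any") n_sig >= 1 else n_sig > n_tis / 2
  dirn <- rep(NA_real_, length(all_ids))
  dirn[biased] <- dir_score[all_ids[biased]]
  # tie on direction: use the largest |stat| among significant tissues
  tie <- which(biased & dirn == 0)
  for (i in tie) {
    s <- sig[sig$gene_id == all_ids[i], ]
    dirn[i] <- sign(s$log2fc[which.max(abs(s$stat))])
  }
  calls <- data.frame(
    pair = all_ids,
    gene_a = sub("\\|.*", "", all_ids), gene_b = sub(".*\\|", "", all_ids),
    n_sig_tissues = as.integer(n_sig),
    class = ifelse(!biased, "unbiased",
                   ifelse(dirn > 0, "A-dominant", "B-dominant")),
    stringsAsFactors = FALSE)
  per_tis_summary <- as.data.frame(table(tissue = pt$tissue,
                                         class = pt$class))
  pooled_summary <- as.data.frame(table(class = calls$class))
  list(calls = calls, per_tissue = pt,
       summary = list(per_tissue = per_tis_summary,
                      pooled = pooled_summary,
                      skipped_pairs = skipped,
                      biased_fraction = mean(calls$class != "unbiased")))
}

#' Singleton expression comparison between subgenomes
#'
#' Wilcoxon rank-sum test of per-gene mean TPM (across samples) between
#' subgenome A and subgenome B singletons.
#'
#' @param tpm TPM matrix.
#' @param map A \code{homoeolog_map}.
#' @return A \code{subdom_test}.
#' @export
singleton_comparison <- function(tpm, map) {
  sa <- intersect(map$singletons_a, rownames(tpm))
  sb <- intersect(map$singletons_b, rownames(tpm))
  if (length(sa) == 0 || length(sb) == 0) {
    stop("both singleton sets must be non-empty")
  }
  ma <- rowMeans(tpm[sa, , drop = FALSE])
  mb <- rowMeans(tpm[sb, , drop = FALSE])
  rank_sum_test(ma, mb)
}

#' Per-subgenome DEG summary
#'
#' @param de Result of \code{\link{nb_differential}} for the condition
#'   contrast.
#' @param subgenome Named subgenome label per gene (all annotated genes;
#'   the denominator of the rate).
#' @return data.frame subgenome, up, down, total, annotated, rate.
#' @export
subgenome_deg_summary <- function(de, subgenome) {
  sub <- subgenome[de$gene_id]
  up <- de$deg & de$log2fc > 0
  dn <- de$deg & de$log2fc < 0
  labs <- sort(unique(subgenome))
  out <- data.frame(
    subgenome = labs,
    up = vapply(labs, function(s) sum(up[sub == s], na.rm = TRUE), 0L),
    down = vapply(labs, function(s) sum(dn[sub == s], na.rm = TRUE), 0L),
    stringsAsFactors = FALSE)
  out$total <- out$up + out$down
  out$annotated <- vapply(labs, function(s) sum(subgenome == s), 0L)
  out$rate <- out$total / out$annotated
  rownames(out) <- NULL
  out
}
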