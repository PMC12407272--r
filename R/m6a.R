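#' Call m6A peaks from windowed IP/input counts
#'
#' Per transcript window, the library-size-normalised IP/input ratio
#' (pseudocount 0.5 for the ratio only) and a Fisher exact test of the
#' window's IP/input counts against the library totals. Windows with
#' ratio >= \code{ratio_min} (inclusive) and p < \code{p_max} (strict)
#' are significant; runs of adjacent significant windows in a gene merge
#' into one peak with count-weighted mean log2 ratio and the minimum
#' window p.
#'
#' @param windows data.frame gene_id, win_index, start, end, ip, input
#'   (single condition; see \code{\link{call_peaks_by_condition}}).
#' @param ratio_min Minimum normalised IP/input ratio.
#' @param p_max P-value threshold.
#' @param ip_lib,input_lib Library sizes; default: column totals.
#' @return data.frame gene_id, tx_start, tx_end, n_windows, log2_ratio,
#'   p, adj_p.
#' @export
call_peaks <- function(windows, ratio_min = 2, p_max = 0.05,
                       ip_lib = NULL, input_lib = NULL) {
  if (is.null(ip_lib)) ip_lib <- sum(windows$ip)
  if (is.null(input_lib)) input_lib <- sum(windows$input)
  if (ip_lib <= 0 || input_lib <= 0) stop("library sizes must be positive")
  ratio <- ((windows$ip + 0.5) / ip_lib) / ((windows$input + 0.5) / input_lib)
  cand <- which(ratio >= ratio_min)
  p <- rep(1, nrow(windows))
  if (length(cand) > 0) {
    p[cand] <- fisher_p2(windows$ip[cand], windows$input[cand],
                         ip_lib - windows$ip[cand],
                         input_lib - windows$input[cand])
  }
  sig <- ratio >= ratio_min & p < p_max
  if (!any(sig)) {
    return(data.frame(gene_id = character(0), tx_start = numeric(0),
                      tx_end = numeric(0), n_windows = integer(0),
                      log2_ratio = numeric(0), p = numeric(0),
                      adj_p = numeric(0), stringsAsFactors = FALSE))
  }
  w <- windows[sig, ]
  o <- order(w$gene_id, w$win_index)
  w <- w[o, ]
  lr <- log2(ratio[sig][o])
  new_run <- c(TRUE, w$gene_id[-1] != w$gene_id[-nrow(w)] |
                 diff(w$win_index) != 1)
  run <- cumsum(new_run)
  wt <- w$ip + w$input
  peaks <- data.frame(
    gene_id = tapply(w$gene_id, run, function(x) x[1]),
    tx_start = as.numeric(tapply(w$start, run, min)),
    tx_end = as.numeric(tapply(w$end, run, max)),
    n_windows = as.integer(tapply(run, run, length)),
    log2_ratio = as.numeric(tapply(lr * wt, run, sum) /
                              tapply(wt, run, sum)),
    p = as.numeric(tapply(p[sig][o], run, min)),
    stringsAsFactors = FALSE)
  peaks$adj_p <- bh_adjust(peaks$p)
  rownames(peaks) <- NULL
  peaks
}

#' Call peaks per condition
#'
#' @param windows Windowed counts with a condition column.
#' @inheritParams call_peaks
#' @return Named list of peak tables, one per condition.
#' @export
call_peaks_by_condition <- function(windows, ratio_min = 2, p_max = 0.05) {
  conds <- unique(windows$condition)
  out <- lapply(conds, function(cc) {
    call_peaks(windows[windows$condition == cc, ], ratio_min, p_max)
  })
  stats::setNames(out, conds)
}

#' Annotate peaks with transcript features
#'
#' Assigns each peak the transcript region (5'UTR, CDS, 3'UTR) with the
#' largest bp overlap; ties break by priority 3'UTR > 5'UTR > CDS.
#' Transcripts without UTRs yield CDS; genes absent from the annotation
#' are kept with feature "unassigned" (with a warning). Also reports
#' observed/expected feature enrichment, where expected is proportional
#' to summed feature lengths.
#'
#' @param peaks Peak table (transcript coordinates).
#' @param gs A \code{gene_set}.
#' @return List with \code{peaks} (plus feature column) and
#'   \code{enrichment} (feature, n, observed_frac, expected_frac,
#'   enrichment).
#' @export
annotate_feature <- function(peaks, gs) {
  lay <- transcript_layout(gs)
  rownames(lay) <- lay$gene_id
  known <- peaks$gene_id %in% lay$gene_id
  if (any(!known)) {
    warning(sum(!known), " peak(s) on genes absent from the annotation; ",
            "feature set to 'unassigned'")
  }
  l <- lay[peaks$gene_id, ]
  ov <- function(a0, a1, b0, b1) pmax(pmin(a1, b1) - pmax(a0, b0), 0)
  o5 <- ov(peaks$tx_start, peaks$tx_end, 0, l$len5)
  oc <- ov(peaks$tx_start, peaks$tx_end, l$len5, l$len5 + l$len_cds)
  o3 <- ov(peaks$tx_start, peaks$tx_end, l$len5 + l$len_cds,
           l$len5 + l$len_cds + l$len3)
  # tie priority 3'UTR > 5'UTR > CDS: compare in that order with >=
  feature <- ifelse(o3 >= o5 & o3 >= oc & o3 > 0, "3'UTR",
                    ifelse(o5 >= oc & o5 > 0, "5'UTR",
                           ifelse(oc > 0, "CDS", "CDS")))
  feature[!known] <- "unassigned"
  peaks$feature <- feature
  tot_len <- c(`5'UTR` = sum(lay$len5), CDS = sum(lay$len_cds),
               `3'UTR` = sum(lay$len3))
  obs <- table(factor(peaks$feature[known],
                      levels = c("5'UTR", "CDS", "3'UTR")))
  enr <- data.frame(feature = names(obs), n = as.integer(obs),
                    observed_frac = as.numeric(obs) / max(sum(obs), 1),
                    expected_frac = as.numeric(tot_len[names(obs)]) /
                      sum(tot_len),
                    stringsAsFactors = FALSE)
  enr$enrichment <- enr$observed_frac / enr$expected_frac
  rownames(enr) <- NULL
  list(peaks = peaks, enrichment = enr)
}

#' Genes-with-peaks counts and peaks-per-gene histogram
#'
#' @param peaks Peak table.
#' @return List with \code{n_genes}, \code{histogram} (peaks-per-gene)
#'   and \code{n_peaks}.
#' @export
peak_gene_summary <- function(peaks) {
  if (nrow(peaks) == 0) {
    return(list(n_genes = 0L, histogram = table(integer(0)), n_peaks = 0L))
  }
  per_gene <- table(peaks$gene_id)
  list(n_genes = length(per_gene), histogram = table(as.integer(per_gene)),
       n_peaks = nrow(peaks))
}

#' Homoeolog sharing of m6A methylation
#'
#' Among methylated genes that belong to homoeolog pairs: a gene is
#' "shared" when both pair members are methylated, otherwise A- or
#' B-specific. Fractions are over methylated pair-member genes.
#'
#' @param peaks Peak table (one condition).
#' @param map A \code{homoeolog_map}.
#' @return data.frame class, n_genes, fraction.
#' @export
homoeolog_sharing <- function(peaks, map) {
  meth_genes <- unique(peaks$gene_id)
  pr <- map$pairs
  a_m <- pr$gene_a %in% meth_genes
  b_m <- pr$gene_b %in% meth_genes
  n_shared <- 2 * sum(a_m & b_m)
  n_a <- sum(a_m & !b_m)
  n_b <- sum(b_m & !a_m)
  tot <- n_shared + n_a + n_b
  data.frame(class = c("shared", "A-specific", "B-specific"),
             n_genes = c(n_shared, n_a, n_b),
             fraction = if (tot > 0) c(n_shared, n_a, n_b) / tot else
               rep(NA_real_, 3),
             stringsAsFactors = FALSE)
}

#' Compare m6A peaks between conditions
#'
#' Peak-number change (per subgenome and overall), methylation-level
#' (peak log2 IP/input ratio) distributions with rank-sum tests between
#' subgenomes and between conditions, and cumulative-distribution export.
#'
#' @param peaks_ctl,peaks_wl Annotated peak tables.
#' @param subgenome Named subgenome label per gene.
#' @return List with \code{counts} (per-subgenome n_ctl, n_wl, delta_frac),
#'   \code{tests} and \code{levels} (long table for ECDF plotting).
#' @export
condition_compare <- function(peaks_ctl, peaks_wl, subgenome) {
  if (nrow(peaks_ctl) == 0) stop("no control peaks")
  sub_c <- subgenome[peaks_ctl$gene_id]
  sub_w <- subgenome[peaks_wl$gene_id]
  labs <- c("A", "B")
  counts <- data.frame(
    subgenome = c(labs, "all"),
    n_ctl = c(vapply(labs, function(s) sum(sub_c == s, na.rm = TRUE), 0L),
              nrow(peaks_ctl)),
    n_wl = c(vapply(labs, function(s) sum(sub_w == s, na.rm = TRUE), 0L),
             nrow(peaks_wl)))
  counts$delta_frac <- (counts$n_wl - counts$n_ctl) / counts$n_ctl
  tests <- list(
    between_conditions = rank_sum_test(peaks_ctl$log2_ratio,
                                       peaks_wl$log2_ratio),
    between_subgenomes_ctl =
      rank_sum_test(peaks_ctl$log2_ratio[sub_c == "A"],
                    peaks_ctl$log2_ratio[sub_c == "B"]),
    between_subgenomes_wl = if (nrow(peaks_wl) > 0) {
      rank_sum_test(peaks_wl$log2_ratio[sub_w == "A"],
                    peaks_wl$log2_ratio[sub_w == "B"])
    } else NULL)
  levels <- rbind(
    data.frame(condition = "CTL", subgenome = sub_c,
               log2_ratio = peaks_ctl$log2_ratio),
    data.frame(condition = "WL", subgenome = sub_w,
               log2_ratio = peaks_wl$log2_ratio))
  rownames(levels) <- NULL
  list(counts = counts, tests = tests, levels = levels)
}

#' Differential m6A methylation over shared peak regions
#'
#' For each region where control and waterlogged peaks of the same gene
#' overlap, sums the window counts over the shared span per condition and
#' contrasts enrichment between conditions with Fisher's exact test on
#' the library-scaled 2x2 table. Differential = BH-adjusted p below
#' \code{fdr} and |delta log2 ratio| >= \code{min_dlfc}.
#'
#' @param windows Windowed counts with condition column (CTL and WL).
#' @param peaks_ctl,peaks_wl Peak tables.
#' @param fdr,min_dlfc Thresholds.
#' @return data.frame per shared region: gene_id, tx_start, tx_end,
#'   log2_ratio_ctl, log2_ratio_wl, dlog2_ratio, p, adj_p, differential.
#' @export
differential_m6a <- function(windows, peaks_ctl, peaks_wl, fdr = 0.05,
                             min_dlfc = 1) {
  empty <- data.frame(gene_id = character(0), tx_start = numeric(0),
                      tx_end = numeric(0), log2_ratio_ctl = numeric(0),
                      log2_ratio_wl = numeric(0), dlog2_ratio = numeric(0),
                      p = numeric(0), adj_p = numeric(0),
                      differential = logical(0))
  if (nrow(peaks_ctl) == 0 || nrow(peaks_wl) == 0) return(empty)
  ov <- merge(peaks_ctl[, c("gene_id", "tx_start", "tx_end")],
              peaks_wl[, c("gene_id", "tx_start", "tx_end")],
              by = "gene_id", suffixes = c("_c", "_w"))
  ov <- ov[pmin(ov$tx_end_c, ov$tx_end_w) >
             pmax(ov$tx_start_c, ov$tx_start_w), ]
  if (nrow(ov) == 0) return(empty)
  # one region per control peak detected in both conditions: the union
  # span of the control peak and every waterlogged peak overlapping it
  # (robust to borderline peaks fragmenting in one condition)
  grp <- paste(ov$gene_id, ov$tx_start_c)
  shared <- data.frame(
    gene_id = tapply(ov$gene_id, grp, function(x) x[1]),
    tx_start = as.numeric(tapply(pmin(ov$tx_start_c, ov$tx_start_w),
                                 grp, min)),
    tx_end = as.numeric(tapply(pmax(ov$tx_end_c, ov$tx_end_w), grp, max)),
    stringsAsFactors = FALSE)
  rownames(shared) <- NULL

  wc <- windows[windows$condition == "CTL", ]
  ww <- windows[windows$condition == "WL", ]
  libs <- c(ip_c = sum(wc$ip), in_c = sum(wc$input),
            ip_w = sum(ww$ip), in_w = sum(ww$input))
  n <- nrow(shared)
  ip_c <- in_c <- ip_w <- in_w <- numeric(n)
  wc_split <- split(wc, wc$gene_id)
  ww_split <- split(ww, ww$gene_id)
  for (i in seq_len(n)) {
    g <- shared$gene_id[i]; s <- shared$tx_start[i]; e <- shared$tx_end[i]
    wci <- wc_split[[g]]; wwi <- ww_split[[g]]
    if (!is.null(wci)) {
      selc <- wci$start < e & wci$end > s
      ip_c[i] <- sum(wci$ip[selc]); in_c[i] <- sum(wci$input[selc])
    }
    if (!is.null(wwi)) {
      selw <- wwi$start < e & wwi$end > s
      ip_w[i] <- sum(wwi$ip[selw]); in_w[i] <- sum(wwi$input[selw])
    }
  }
  zero_track <- ip_c == 0 | in_c == 0 | ip_w == 0 | in_w == 0
  lr_c <- log2(((ip_c + 0.5) / libs["ip_c"]) / ((in_c + 0.5) / libs["in_c"]))
  lr_w <- log2(((ip_w + 0.5) / libs["ip_w"]) / ((in_w + 0.5) / libs["in_w"]))
  # correct only the *relative* IP/input library imbalance between the
  # conditions, keeping counts as large as possible for power
  s_c <- libs["ip_c"] / libs["in_c"]; s_w <- libs["ip_w"] / libs["in_w"]
  in_c_s <- round(in_c * s_c / max(s_c, s_w))
  in_w_s <- round(in_w * s_w / max(s_c, s_w))
  p <- fisher_p2(ip_c, in_c_s, ip_w, in_w_s)
  adj <- bh_adjust(p)
  d <- lr_w - lr_c
  out <- data.frame(gene_id = shared$gene_id, tx_start = shared$tx_start,
                    tx_end = shared$tx_end,
                    log2_ratio_ctl = as.numeric(lr_c),
                    log2_ratio_wl = as.numeric(lr_w),
                    dlog2_ratio = as.numeric(d), p = p, adj_p = adj,
                    differential = adj < fdr & abs(d) >= min_dlfc,
                    stringsAsFactors = FALSE)
  attr(out, "zero_track_pseudocount") <- sum(zero_track)
  rownames(out) <- NULL
  out
}

#' Integrate differential expression with differential m6A
#'
#' Cross-tabulates genes significant in both analyses into
#' (m6A up/down) x (expression up/down) quadrants and tests direction
#' concordance with Fisher's exact test (odds ratio < 1 indicates
#' repressive coupling: m6A loss with expression gain).
#'
#' @param diff_m6a Output of \code{\link{differential_m6a}}.
#' @param de Output of \code{\link{nb_differential}}.
#' @return List with \code{table} (2x2), \code{test}, \code{quadrants}
#'   (per-quadrant gene lists).
#' @export
integrate_de_m6a <- function(diff_m6a, de) {
  m <- diff_m6a[diff_m6a$differential, ]
  e <- de[de$deg, ]
  common <- intersect(m$gene_id, e$gene_id)
  if (length(common) == 0) {
    warning("no gene is significant in both analyses")
    tab <- matrix(0L, 2, 2, dimnames = list(m6a = c("up", "down"),
                                            expr = c("up", "down")))
    return(list(table = tab, test = NULL,
                quadrants = list()))
  }
  m6a_dir <- ifelse(m$dlog2_ratio[match(common, m$gene_id)] > 0,
                    "up", "down")
  de_dir <- ifelse(e$log2fc[match(common, e$gene_id)] > 0, "up", "down")
  tab <- table(factor(m6a_dir, c("up", "down")),
               factor(de_dir, c("up", "down")))
  names(dimnames(tab)) <- c("m6a", "expr")
  tst <- fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  quads <- split(common, paste0("m6a_", m6a_dir, ".expr_", de_dir))
  list(table = tab, test = tst, quadrants = quads)
}
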