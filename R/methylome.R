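as_granges <- function(d, chrom = "chrom", start = "start", end = "end",
                       strand = NULL) {
  # internal 0-based half-open -> IRanges 1-based closed
  st <- if (is.null(strand)) "*" else d[[strand]]
  GenomicRanges::GRanges(d[[chrom]],
                         IRanges::IRanges(d[[start]] + 1, d[[end]]),
                         strand = st)
}

#' TE genomic content per subgenome
#'
#' Fraction of each subgenome covered by (merged) TE intervals.
#'
#' @param tes TE intervals (data.frame chrom, start, end).
#' @param genome A \code{subdom_genome}.
#' @return data.frame subgenome, te_bp, genome_bp, fraction.
#' @export
te_content <- function(tes, genome) {
  gr <- GenomicRanges::reduce(as_granges(tes))
  chrom_sub <- stats::setNames(genome$subgenome, genome$chrom)
  cov <- tapply(BiocGenerics::width(gr),
                chrom_sub[as.character(GenomicRanges::seqnames(gr))], sum)
  labs <- sort(unique(genome$subgenome))
  out <- data.frame(
    subgenome = labs,
    te_bp = as.numeric(ifelse(labs %in% names(cov), cov[labs], 0)),
    genome_bp = vapply(labs, function(s) {
      sum(genome$length[genome$subgenome == s])
    }, 0))
  out$fraction <- out$te_bp / out$genome_bp
  rownames(out) <- NULL
  out
}

#' Gene-to-nearest-TE distances and between-subgenome test
#'
#' Distance is the gap in bp between the gene span and the nearest TE on
#' the same chromosome (0 when overlapping or abutting); genes on
#' chromosomes without any TE get NA and are excluded from the test.
#'
#' @param gs A \code{gene_set}.
#' @param tes TE intervals.
#' @return List with \code{distances} (gene_id, subgenome, distance),
#'   \code{medians} (per subgenome) and \code{test} (rank-sum A vs B).
#' @export
nearest_te_distance <- function(gs, tes) {
  genes <- gs$genes
  gg <- as_granges(genes)
  tg <- as_granges(tes)
  d <- rep(NA_real_, nrow(genes))
  hits <- GenomicRanges::distanceToNearest(gg, tg)
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  n_undef <- sum(is.na(d))
  res <- data.frame(gene_id = genes$gene_id, subgenome = genes$subgenome,
                    distance = d, stringsAsFactors = FALSE)
  da <- d[genes$subgenome == "A" & !is.na(d)]
  db <- d[genes$subgenome == "B" & !is.na(d)]
  med <- data.frame(subgenome = c("A", "B"),
                    median_bp = c(stats::median(da), stats::median(db)))
  tst <- if (length(da) > 0 && length(db) > 0) rank_sum_test(da, db) else
    NULL
  list(distances = res, medians = med, test = tst, n_undefined = n_undef)
}

#' Solo:intact LTR ratio per subgenome
#'
#' @param ltrs data.frame id, subgenome, kind (solo/intact),
#'   ltr_divergence, family.
#' @return data.frame subgenome, solo, intact, ratio.
#' @export
solo_intact_ratio <- function(ltrs) {
  labs <- sort(unique(ltrs$subgenome))
  out <- data.frame(
    subgenome = labs,
    solo = vapply(labs, function(s) {
      sum(ltrs$kind == "solo" & ltrs$subgenome == s)
    }, 0L),
    intact = vapply(labs, function(s) {
      sum(ltrs$kind == "intact" & ltrs$subgenome == s)
    }, 0L))
  if (any(out$intact == 0)) {
    stop("no intact LTR in subgenome ", out$subgenome[out$intact == 0][1])
  }
  out$ratio <- out$solo / out$intact
  rownames(out) <- NULL
  out
}

#' LTR retrotransposon insertion age
#'
#' Age in years from the divergence between the element's two long
#' terminal repeats: \code{age = divergence / (2 * mu)}.
#'
#' @param divergence Per-site substitutions between the paired LTRs.
#' @param mu Substitution rate per site per year (> 0).
#' @return Age in years.
#' @export
ltr_insertion_age <- function(divergence, mu) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(divergence < 0, na.rm = TRUE)) stop("divergence must be >= 0")
  divergence / (2 * mu)
}

#' Global weighted methylation level per subgenome and context
#'
#' Weighted level = sum(mc) / sum(total) over all covered cytosines of a
#' (subgenome, context) stratum.
#'
#' @param meth Methylation table (see \code{\link{read_methylation}}).
#' @param genome A \code{subdom_genome}.
#' @return data.frame subgenome, context, level, n_sites.
#' @export
global_methylation <- function(meth, genome) {
  sub <- stats::setNames(genome$subgenome, genome$chrom)[meth$chrom]
  use <- meth$total_count > 0
  key <- paste(sub, meth$context)
  mc <- tapply(meth$mc_count[use], key[use], sum)
  tot <- tapply(meth$total_count[use], key[use], sum)
  all_keys <- as.vector(outer(sort(unique(sub)), c("CG", "CHG", "CHH"),
                              paste))
  out <- data.frame(
    subgenome = sub("^(\\S+) .*", "\\1", all_keys),
    context = sub("^\\S+ ", "", all_keys),
    level = as.numeric(ifelse(all_keys %in% names(mc),
                              mc[all_keys] / tot[all_keys], NA)),
    n_sites = as.integer(tapply(use, key, sum)[all_keys]))
  out$n_sites[is.na(out$n_sites)] <- 0L
  rownames(out) <- NULL
  out
}

#' Methylation metaprofile over regions with flanks
#'
#' Length-normalised body bins plus fixed-bp flank bins, strand-aware
#' (upstream = 5' side for stranded regions). Per bin and context, the
#' weighted methylation level across all regions; bins without covered
#' cytosines are NA, never zero-filled.
#'
#' @param meth Methylation table.
#' @param regions data.frame chrom, start, end and optionally strand.
#' @param flank_bp Flank width each side, bp.
#' @param body_bins,flank_bins Bin counts.
#' @return data.frame context, bin_index, bin_kind (upstream/body/
#'   downstream), level, n (covered sites), of class
#'   \code{subdom_metaprofile}.
#' @export
metaprofile <- function(meth, regions, flank_bp = 2000, body_bins = 20,
                        flank_bins = 20) {
  if (nrow(regions) == 0) stop("regions must be non-empty")
  strand <- if ("strand" %in% names(regions)) regions$strand else
    rep("+", nrow(regions))
  strand[!strand %in% c("+", "-")] <- "+"
  short <- sum(regions$end - regions$start < body_bins)
  if (short > 0) {
    message(short, " region(s) shorter than body_bins; short bodies are",
            " spread over repeated bins")
  }
  ext <- data.frame(chrom = regions$chrom,
                    start = pmax(regions$start - flank_bp, 0),
                    end = regions$end + flank_bp)
  site_gr <- GenomicRanges::GRanges(meth$chrom,
                                    IRanges::IRanges(meth$pos + 1,
                                                     meth$pos + 1))
  hits <- GenomicRanges::findOverlaps(site_gr, as_granges(ext))
  qi <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
  use <- meth$total_count[qi] > 0
  qi <- qi[use]; ri <- ri[use]
  pos <- meth$pos[qi]
  rs <- regions$start[ri]; re <- regions$end[ri]; str <- strand[ri]
  body_len <- re - rs
  total_bins <- 2 * flank_bins + body_bins
  bin <- integer(length(qi))
  before <- pos < rs
  after <- pos >= re
  inside <- !before & !after
  fb <- flank_bp / flank_bins
  # left flank (genomic): bins counted from the region edge outward
  bl <- flank_bins - pmin(floor((rs[before] - pos[before] - 1) / fb),
                          flank_bins - 1)
  bin[before] <- bl
  bin[inside] <- flank_bins +
    pmin(floor((pos[inside] - rs[inside]) / body_len[inside] * body_bins),
         body_bins - 1) + 1
  br <- pmin(floor((pos[after] - re[after]) / fb), flank_bins - 1) + 1
  bin[after] <- flank_bins + body_bins + br
  # strand: reverse the whole profile for minus-strand regions
  neg <- str == "-"
  bin[neg] <- total_bins + 1L - bin[neg]
  ctx <- meth$context[qi]
  key <- paste(ctx, bin)
  mc <- tapply(meth$mc_count[qi], key, sum)
  tot <- tapply(meth$total_count[qi], key, sum)
  n <- tapply(rep(1, length(qi)), key, sum)
  grid <- expand.grid(context = c("CG", "CHG", "CHH"),
                      bin_index = seq_len(total_bins),
                      stringsAsFactors = FALSE)
  gk <- paste(grid$context, grid$bin_index)
  out <- data.frame(
    context = grid$context, bin_index = grid$bin_index,
    bin_kind = ifelse(grid$bin_index <= flank_bins, "upstream",
                      ifelse(grid$bin_index <= flank_bins + body_bins,
                             "body", "downstream")),
    level = as.numeric(ifelse(gk %in% names(mc), mc[gk] / tot[gk], NA)),
    n = as.integer(ifelse(gk %in% names(n), n[gk], 0)))
  out <- out[order(out$context, out$bin_index), ]
  rownames(out) <- NULL
  class(out) <- c("subdom_metaprofile", "data.frame")
  attr(out, "flank_bins") <- flank_bins
  attr(out, "body_bins") <- body_bins
  out
}

#' Plot a methylation metaprofile
#'
#' One line per context over upstream flank, body and downstream flank.
#'
#' @param x A \code{subdom_metaprofile}.
#' @param ... Passed to \code{matplot}.
#' @export
plot.subdom_metaprofile <- function(x, ...) {
  fb <- attr(x, "flank_bins"); bb <- attr(x, "body_bins")
  ctxs <- unique(x$context)
  m <- sapply(ctxs, function(cc) x$level[x$context == cc])
  graphics::matplot(seq_len(nrow(m)), m, type = "l", lty = 1,
                    xlab = "bin", ylab = "methylation level",
                    ...)
  graphics::abline(v = c(fb + 0.5, fb + bb + 0.5), lty = 3)
  graphics::legend("topright", legend = ctxs, lty = 1,
                   col = seq_along(ctxs), bty = "n")
  invisible(x)
}
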