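#' Pair homoeologs by collinear anchor chaining
#'
#' Chains anchor hits that are collinear in gene-rank space (per
#' chromosome pair, either orientation), with at most \code{max_gap}
#' intervening genes between successive anchors; blocks with fewer than
#' \code{min_block} anchors are discarded. Within each block, genes are
#' assigned one-to-one by descending similarity; unpaired genes lying
#' inside a block's span become singletons of their subgenome, genes
#' outside any block remain unassigned.
#'
#' @param gs A \code{gene_set} containing both subgenomes.
#' @param hits data.frame gene_a, gene_b, similarity. Duplicate
#'   (gene_a, gene_b) hits are collapsed to the maximum similarity.
#' @param max_gap Maximum intervening genes between chained anchors.
#' @param min_block Minimum anchors per retained block.
#' @return A \code{homoeolog_map}: list with \code{pairs} (gene_a, gene_b,
#'   block_id, similarity), \code{singletons_a}, \code{singletons_b},
#'   \code{unassigned}.
#' @export
pair_homoeologs <- function(gs, hits, max_gap = 10, min_block = 5) {
  genes <- gs$genes
  ga <- genes[genes$subgenome == "A", ]
  gb <- genes[genes$subgenome == "B", ]
  rank_of <- function(g) {
    o <- order(g$chrom, g$start)
    r <- integer(nrow(g))
    r[o] <- stats::ave(seq_along(o), g$chrom[o], FUN = seq_along)
    stats::setNames(r, g$gene_id)
  }
  rka <- rank_of(ga); rkb <- rank_of(gb)
  chra <- stats::setNames(ga$chrom, ga$gene_id)
  chrb <- stats::setNames(gb$chrom, gb$gene_id)

  if (nrow(hits) > 0) {
    bad <- !(hits$gene_a %in% ga$gene_id) | !(hits$gene_b %in% gb$gene_id)
    if (any(bad)) stop("anchor hit references unknown gene: ",
                       hits$gene_a[which(bad)[1]])
    key <- paste(hits$gene_a, hits$gene_b)
    if (anyDuplicated(key)) {
      message("collapsing ", sum(duplicated(key)),
              " duplicate anchor hit(s) to max similarity")
      o <- order(key, -hits$similarity)
      hits <- hits[o, ][!duplicated(key[o]), ]
    }
  }

  pairs_out <- list()
  block_spans <- list()
  block_id <- 0L
  if (nrow(hits) > 0) {
    hits$ra <- unname(rka[hits$gene_a])
    hits$rb <- unname(rkb[hits$gene_b])
    hits$ca <- unname(chra[hits$gene_a])
    hits$cb <- unname(chrb[hits$gene_b])
    for (grp in split(hits, paste(hits$ca, hits$cb))) {
      blocks <- chain_anchors(grp$ra, grp$rb, max_gap)
      for (bl in blocks) {
        if (length(bl) < min_block) next
        block_id <- block_id + 1L
        b <- grp[bl, ]
        # one-to-one by descending similarity
        o <- order(-b$similarity, b$ra)
        used_a <- used_b <- character(0)
        sel <- logical(nrow(b))
        for (i in o) {
          if (b$gene_a[i] %in% used_a || b$gene_b[i] %in% used_b) next
          sel[i] <- TRUE
          used_a <- c(used_a, b$gene_a[i]); used_b <- c(used_b, b$gene_b[i])
        }
        pb <- b[sel, c("gene_a", "gene_b", "similarity")]
        pb$block_id <- block_id
        pairs_out[[block_id]] <- pb
        block_spans[[block_id]] <- list(
          ca = b$ca[1], cb = b$cb[1],
          ra = range(b$ra), rb = range(b$rb))
      }
    }
  }
  pairs <- if (length(pairs_out) > 0) do.call(rbind, pairs_out) else
    data.frame(gene_a = character(0), gene_b = character(0),
               similarity = numeric(0), block_id = integer(0))
  rownames(pairs) <- NULL

  in_span_a <- rep(FALSE, nrow(ga)); names(in_span_a) <- ga$gene_id
  in_span_b <- rep(FALSE, nrow(gb)); names(in_span_b) <- gb$gene_id
  for (sp in block_spans) {
    in_span_a[chra == sp$ca & rka >= sp$ra[1] & rka <= sp$ra[2]] <- TRUE
    in_span_b[chrb == sp$cb & rkb >= sp$rb[1] & rkb <= sp$rb[2]] <- TRUE
  }
  if (nrow(pairs) == 0) {
    # no collinear block at all: every gene is a singleton of its
    # subgenome (nothing was retained in duplicate)
    singletons_a <- ga$gene_id
    singletons_b <- gb$gene_id
    unassigned <- character(0)
  } else {
    singletons_a <- setdiff(names(in_span_a)[in_span_a], pairs$gene_a)
    singletons_b <- setdiff(names(in_span_b)[in_span_b], pairs$gene_b)
    unassigned <- setdiff(genes$gene_id,
                          c(pairs$gene_a, pairs$gene_b,
                            singletons_a, singletons_b))
  }
  structure(list(pairs = pairs, singletons_a = singletons_a,
                 singletons_b = singletons_b, unassigned = unassigned),
            class = "homoeolog_map")
}

# Chain anchors collinear in rank space. Returns a list of integer index
# vectors (into ra/rb), each a block. DP over anchors sorted by ra, run
# separately for the two orientations; chains are extracted greedily by
# score without reusing anchors.
chain_anchors <- function(ra, rb, max_gap) {
  n <- length(ra)
  if (n == 0) return(list())
  step <- max_gap + 1
  chains <- list()
  avail <- rep(TRUE, n)
  for (orient in c(1, -1)) {
    repeat {
      idx <- which(avail)
      if (length(idx) == 0) break
      o <- idx[order(ra[idx], orient * rb[idx])]
      m <- length(o)
      dp <- rep(1L, m); prev <- rep(0L, m)
      lo <- 1L
      for (i in seq_len(m)) {
        while (ra[o[lo]] < ra[o[i]] - step) lo <- lo + 1L
        if (i > lo) {
          j0 <- lo:(i - 1L)
          da <- ra[o[i]] - ra[o[j0]]
          db <- (rb[o[i]] - rb[o[j0]]) * orient
          cand <- j0[da > 0 & db > 0 & db <= step]
          if (length(cand) > 0) {
            j <- cand[which.max(dp[cand])]
            dp[i] <- dp[j] + 1L
            prev[i] <- j
          }
        }
      }
      best <- which.max(dp)
      if (dp[best] < 2) break   # no multi-anchor chain left in this orientation
      chain <- integer(0)
      k <- best
      while (k != 0) { chain <- c(o[k], chain); k <- prev[k] }
      chains[[length(chains) + 1]] <- chain
      avail[chain] <- FALSE
    }
  }
  # leftover isolated anchors become length-1 chains (dropped by min_block)
  for (i in which(avail)) chains[[length(chains) + 1]] <- i
  chains
}

#' Fractionation profile in sliding windows of ancestral gene slots
#'
#' Per window of \code{window_genes} consecutive ancestral slots (per
#' ancestral chromosome), the fraction of slots retained in subgenome A,
#' in B, and in both.
#'
#' @param ancestral_order data.frame slot, anc_chrom, slot_order, gene_a,
#'   gene_b (NA where the copy was lost), e.g. the simulator's
#'   \code{ancestral_order.tsv} or an outgroup-derived ordering.
#' @param retained_a,retained_b Optional character vectors of gene ids
#'   actually present (defaults: non-NA entries).
#' @param window_genes Window size in slots.
#' @param step Step between window starts, in slots.
#' @return data.frame anc_chrom, start_slot, rate_a, rate_b, rate_both.
#' @export
fractionation_profile <- function(ancestral_order, retained_a = NULL,
                                  retained_b = NULL, window_genes = 100,
                                  step = window_genes %/% 2) {
  ao <- ancestral_order[order(ancestral_order$anc_chrom,
                              ancestral_order$slot_order), ]
  in_a <- !is.na(ao$gene_a) & ao$gene_a != ""
  in_b <- !is.na(ao$gene_b) & ao$gene_b != ""
  if (!is.null(retained_a)) in_a <- in_a & ao$gene_a %in% retained_a
  if (!is.null(retained_b)) in_b <- in_b & ao$gene_b %in% retained_b
  step <- max(1L, as.integer(step))
  out <- list()
  for (cc in unique(ao$anc_chrom)) {
    sel <- ao$anc_chrom == cc
    a <- in_a[sel]; b <- in_b[sel]
    n <- length(a)
    w <- min(window_genes, n)
    if (w < window_genes) {
      message("chromosome ", cc, " has fewer slots (", n,
              ") than the window; using one truncated window")
    }
    starts <- unique(c(seq(1L, max(n - w + 1L, 1L), by = step),
                       max(n - w + 1L, 1L)))
    out[[length(out) + 1]] <- data.frame(
      anc_chrom = cc, start_slot = starts,
      rate_a = vapply(starts, function(s) mean(a[s:(s + w - 1)]), 0),
      rate_b = vapply(starts, function(s) mean(b[s:(s + w - 1)]), 0),
      rate_both = vapply(starts, function(s) mean(a[s:(s + w - 1)] &
                                                    b[s:(s + w - 1)]), 0))
  }
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  prof
}

#' Test for biased fractionation between subgenomes
#'
#' Paired Wilcoxon signed-rank test of per-window retention rates
#' (rate_a vs rate_b) across the fractionation profile.
#'
#' @param profile Output of \code{\link{fractionation_profile}}.
#' @return A \code{subdom_test}; \code{effect} is the mean
#'   rate_a - rate_b difference.
#' @export
retention_balance_test <- function(profile) {
  if (nrow(profile) < 2) stop("at least 2 windows are required")
  d <- profile$rate_a - profile$rate_b
  eff <- mean(d)
  if (all(d == 0)) {
    return(new_test_result(0, 1, 0,
                           "paired Wilcoxon signed-rank (degenerate)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(profile$rate_a, profile$rate_b,
                                            paired = TRUE, exact = FALSE))
  new_test_result(unname(wt$statistic), wt$p.value, eff,
                  "paired Wilcoxon signed-rank test of window retention")
}

#' @export
print.homoeolog_map <- function(x, ...) {
  cat("homoeolog map:", nrow(x$pairs), "pairs,",
      length(x$singletons_a), "A singletons,",
      length(x$singletons_b), "B singletons,",
      length(x$unassigned), "unassigned\n")
  invisible(x)
}
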