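#' Classify ACR positions relative to genes
#'
#' Priority: genic (overlaps any gene body) > proximal (within
#' \code{proximal_bp} upstream of a TSS, strand-aware, inclusive
#' boundary) > distal. Each ACR is annotated with the gene whose TSS is
#' closest; an ACR inside two genes' proximal windows is assigned to the
#' nearest TSS only.
#'
#' @param acrs data.frame chrom, start, end (plus any id columns, kept).
#' @param gs A \code{gene_set}.
#' @param proximal_bp Proximal window size, bp.
#' @param flank_mode "upstream" classifies only the strand-aware upstream
#'   window as proximal; "both" uses both flanks of the gene.
#' @return Input data.frame plus position_class, nearest_gene,
#'   tss_distance.
#' @export
classify_position <- function(acrs, gs, proximal_bp = 5000,
                              flank_mode = c("upstream", "both")) {
  flank_mode <- match.arg(flank_mode)
  genes <- gs$genes
  ag <- as_granges(acrs)
  gg <- as_granges(genes)
  genic <- GenomicRanges::countOverlaps(ag, gg) > 0

  tssg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$tss + 1,
                                                  genes$tss + 1))
  nh <- GenomicRanges::distanceToNearest(ag, tssg)
  nearest_gene <- rep(NA_character_, nrow(acrs))
  tss_dist <- rep(NA_real_, nrow(acrs))
  nearest_gene[S4Vectors::queryHits(nh)] <-
    genes$gene_id[S4Vectors::subjectHits(nh)]
  tss_dist[S4Vectors::queryHits(nh)] <- S4Vectors::mcols(nh)$distance

  # strand-aware upstream gap from a TSS to an ACR:
  #   + gene: gap = tss - acr_end   (>= 0 when the ACR is fully upstream)
  #   - gene: gap = acr_start - tss - 1
  up <- upstream_gaps(acrs, genes, proximal_bp, flank_mode)
  proximal <- rep(FALSE, nrow(acrs))
  proximal[up$acr_i] <- TRUE
  # proximal assignment goes to the gene with the nearest TSS among the
  # windows the ACR falls in
  best <- tapply(seq_len(nrow(up)), up$acr_i, function(ii) {
    ii[which.min(up$tss_abs_dist[ii])]
  })
  bi <- as.integer(names(best))
  nearest_gene[bi] <- up$gene_id[unlist(best)]
  tss_dist[bi] <- up$tss_abs_dist[unlist(best)]

  acrs$position_class <- ifelse(genic, "genic",
                                ifelse(proximal, "proximal", "distal"))
  acrs$nearest_gene <- nearest_gene
  acrs$tss_distance <- tss_dist
  acrs
}

# ACR x gene pairs where the ACR lies in the gene's proximal window
upstream_gaps <- function(acrs, genes, proximal_bp, flank_mode) {
  # windows as GRanges covering [tss - proximal_bp, tss) upstream (strand
  # aware); inclusive boundary handled by extending one bp
  plus <- genes$strand == "+"
  # windows cover every base at upstream gap 0..proximal_bp (inclusive)
  if (flank_mode == "upstream") {
    ws <- ifelse(plus, genes$tss - proximal_bp - 1, genes$tss + 1)
    we <- ifelse(plus, genes$tss, genes$tss + proximal_bp + 2)
  } else {
    ws <- genes$tss - proximal_bp - 1
    we <- genes$tss + proximal_bp + 2
  }
  ws <- pmax(ws, 0)
  wg <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(ws + 1, we))
  ag <- as_granges(acrs)
  h <- GenomicRanges::findOverlaps(ag, wg)
  qi <- S4Vectors::queryHits(h); gi <- S4Vectors::subjectHits(h)
  tss <- genes$tss[gi]
  data.frame(acr_i = qi, gene_id = genes$gene_id[gi],
             tss_abs_dist = pmin(abs(tss - acrs$start[qi]),
                                 abs(tss - (acrs$end[qi] - 1))),
             stringsAsFactors = FALSE)
}

#' Proximal ACRs per gene and between-subgenome comparison
#'
#' Counts proximal ACRs assigned to each gene (zero-filled over all
#' annotated genes), the per-subgenome normalised rate (total proximal
#' ACRs / genes) and a rank-sum test of the per-gene counts.
#'
#' @param acr_class Output of \code{\link{classify_position}}.
#' @param gs A \code{gene_set}.
#' @return List with \code{per_gene}, \code{rates} and \code{test}.
#' @export
acr_per_gene <- function(acr_class, gs) {
  genes <- gs$genes
  prox <- acr_class[acr_class$position_class == "proximal", ]
  if ("acr_id" %in% names(prox)) {
    # tissue-expanded tables carry one row per (ACR, tissue); a locus
    # counts once per gene
    prox <- prox[!duplicated(prox$acr_id), ]
  }
  cnt <- table(factor(prox$nearest_gene, levels = genes$gene_id))
  per_gene <- data.frame(gene_id = genes$gene_id,
                         subgenome = genes$subgenome,
                         n_proximal = as.integer(cnt),
                         stringsAsFactors = FALSE)
  labs <- sort(unique(genes$subgenome))
  rates <- data.frame(
    subgenome = labs,
    n_acr = vapply(labs, function(s) {
      sum(per_gene$n_proximal[per_gene$subgenome == s])
    }, 0L),
    n_genes = vapply(labs, function(s) sum(genes$subgenome == s), 0L))
  rates$rate <- rates$n_acr / rates$n_genes
  rownames(rates) <- NULL
  tst <- rank_sum_test(per_gene$n_proximal[per_gene$subgenome == "A"],
                       per_gene$n_proximal[per_gene$subgenome == "B"])
  list(per_gene = per_gene, rates = rates, test = tst)
}

#' Classify ACR conservation between subgenomes
#'
#' Each ACR is projected into the partner subgenome through its nearest
#' homoeologous gene anchor (TSS offset preserved, strand-aware) and
#' called conserved when a partner-subgenome ACR of the same tissue
#' overlaps the projection by at least \code{min_overlap} bp; otherwise
#' subgenome-specific. ACRs anchored on singletons are unprojectable and
#' classed specific with the no-anchor flag.
#'
#' @param acr_class ACRs with nearest_gene assigned (see
#'   \code{\link{classify_position}}); must carry columns acr_id, tissue
#'   and subgenome.
#' @param gs A \code{gene_set}.
#' @param map A \code{homoeolog_map}.
#' @param min_overlap Minimum projected overlap, bp.
#' @return Input plus conservation_class (conserved/A-specific/
#'   B-specific), no_anchor flag, partner_acr, and the projected
#'   coordinates (proj_chrom, proj_start, proj_end).
#' @export
classify_conservation <- function(acr_class, gs, map, min_overlap = 1) {
  genes <- gs$genes
  rownames(genes) <- genes$gene_id
  partner <- c(stats::setNames(map$pairs$gene_b, map$pairs$gene_a),
               stats::setNames(map$pairs$gene_a, map$pairs$gene_b))
  a <- acr_class
  anchor <- a$nearest_gene
  pg <- unname(partner[anchor])
  a$no_anchor <- is.na(pg)

  # transcript-frame offsets of the ACR relative to the anchor TSS
  ga <- genes[anchor, ]
  plus_a <- ga$strand == "+"
  u <- ifelse(plus_a, a$start - ga$tss, ga$tss + 1 - a$end)
  v <- ifelse(plus_a, a$end - ga$tss, ga$tss + 1 - a$start)
  gp <- genes[ifelse(is.na(pg), anchor, pg), ]  # placeholder rows for NA
  plus_p <- gp$strand == "+"
  ps <- ifelse(plus_p, gp$tss + u, gp$tss + 1 - v)
  pe <- ifelse(plus_p, gp$tss + v, gp$tss + 1 - u)
  a$proj_chrom <- ifelse(a$no_anchor, NA_character_, gp$chrom)
  a$proj_start <- ifelse(a$no_anchor, NA_real_, ps)
  a$proj_end <- ifelse(a$no_anchor, NA_real_, pe)

  a$conservation_class <- paste0(a$subgenome, "-specific")
  a$partner_acr <- NA_character_
  proj_ok <- which(!a$no_anchor & !is.na(a$proj_start) & a$proj_start >= 0)
  if (length(proj_ok) > 0) {
    pgr <- GenomicRanges::GRanges(a$proj_chrom[proj_ok],
                                  IRanges::IRanges(a$proj_start[proj_ok] + 1,
                                                   a$proj_end[proj_ok]))
    agr <- as_granges(a)
    h <- GenomicRanges::findOverlaps(pgr, agr,
                                     minoverlap = as.integer(min_overlap))
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    i <- proj_ok[qi]
    good <- a$tissue[si] == a$tissue[i] &
      a$subgenome[si] != a$subgenome[i]
    i <- i[good]; si <- si[good]
    first <- !duplicated(i)
    a$conservation_class[i[first]] <- "conserved"
    a$partner_acr[i[first]] <- a$acr_id[si[first]]
  }
  a
}

#' Variant density in conserved vs specific ACRs
#'
#' Variants overlapping each ACR or its partner-subgenome projection,
#' normalised per kb of ACR length, compared between specific and
#' conserved ACRs by rank-sum test.
#'
#' @param acr_cons Output of \code{\link{classify_conservation}}.
#' @param variants Variant table (see \code{\link{read_variants}}).
#' @return List with \code{per_acr} and \code{test}.
#' @export
acr_variant_density <- function(acr_cons, variants) {
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  n_self <- GenomicRanges::countOverlaps(as_granges(acr_cons), vg)
  n_proj <- rep(0L, nrow(acr_cons))
  ok <- which(!is.na(acr_cons$proj_start) & acr_cons$proj_start >= 0)
  if (length(ok) > 0) {
    pg <- GenomicRanges::GRanges(acr_cons$proj_chrom[ok],
                                 IRanges::IRanges(acr_cons$proj_start[ok] + 1,
                                                  acr_cons$proj_end[ok]))
    n_proj[ok] <- GenomicRanges::countOverlaps(pg, vg)
  }
  per_acr <- data.frame(
    acr_id = acr_cons$acr_id,
    conservation_class = acr_cons$conservation_class,
    n_variants = n_self + n_proj,
    density_per_kb = (n_self + n_proj) /
      ((acr_cons$end - acr_cons$start) / 1000),
    stringsAsFactors = FALSE)
  spec <- per_acr$density_per_kb[per_acr$conservation_class != "conserved"]
  cons <- per_acr$density_per_kb[per_acr$conservation_class == "conserved"]
  tst <- if (length(spec) > 0 && length(cons) > 0) {
    rank_sum_test(spec, cons)
  } else NULL
  list(per_acr = per_acr, test = tst)
}

#' Progenitor ancestry attribution of specific-ACR variants
#'
#' A variant in a subgenome-specific ACR "matches" when the allele of the
#' ACR-carrying subgenome equals the corresponding progenitor's allele
#' (subgenome A vs progenitor A, subgenome B vs progenitor B). Variants
#' with a missing genotype on either side are excluded from numerator and
#' denominator.
#'
#' @param variants Variant table.
#' @param acr_cons Classified ACRs; only non-conserved ACRs are used.
#' @return List with \code{fraction}, \code{matches}, \code{informative}.
#' @export
ancestry_attribution <- function(variants, acr_cons) {
  spec <- acr_cons[acr_cons$conservation_class != "conserved", ]
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  h <- GenomicRanges::findOverlaps(vg, as_granges(spec))
  vi <- S4Vectors::queryHits(h)
  carrier <- spec$subgenome[S4Vectors::subjectHits(h)]
  dup <- duplicated(vi)   # a variant counts once even under two ACRs
  vi <- vi[!dup]; carrier <- carrier[!dup]
  sub_allele <- ifelse(carrier == "A", variants$subA[vi], variants$subB[vi])
  prog_allele <- ifelse(carrier == "A", variants$progA[vi],
                        variants$progB[vi])
  inf <- !is.na(sub_allele) & !is.na(prog_allele)
  if (sum(inf) == 0) stop("no informative variant in specific ACR regions")
  matches <- sum(sub_allele[inf] == prog_allele[inf])
  list(fraction = matches / sum(inf), matches = matches,
       informative = sum(inf))
}

#' Tissue-specific and constitutive ACRs with gene-set enrichment
#'
#' Merges ACRs across tissues into loci; a locus present (>= 1 bp
#' overlap) in every tissue is constitutive, a locus in exactly one
#' tissue is specific to it. Per tissue, the top \code{top_n} specific
#' loci ranked by peak score (ties: length, then coordinate) are kept and
#' their nearest genes tested for term enrichment against a user term
#' map.
#'
#' @param acr_class Classified ACRs with columns tissue, score,
#'   nearest_gene.
#' @param term_map data.frame gene_id, term.
#' @param top_n Specific loci kept per tissue.
#' @return List with \code{constitutive} (locus table), \code{specific}
#'   (per-tissue ranked loci) and \code{enrichment} (term tests with BH
#'   adjustment).
#' @export
tissue_specific_acrs <- function(acr_class, term_map = NULL, top_n = 1000) {
  tissues <- sort(unique(acr_class$tissue))
  if (length(tissues) < 2) stop("at least 2 tissues are required")
  gr <- as_granges(acr_class)
  loci <- GenomicRanges::reduce(gr)
  h <- GenomicRanges::findOverlaps(loci, gr)
  li <- S4Vectors::queryHits(h); ai <- S4Vectors::subjectHits(h)
  tis_per_locus <- tapply(acr_class$tissue[ai], li,
                          function(x) unique(x), simplify = FALSE)
  n_tis <- lengths(tis_per_locus)
  score_per_locus <- tapply(acr_class$score[ai], li, max)
  gene_per_locus <- tapply(acr_class$nearest_gene[ai], li,
                           function(x) x[1])
  ld <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(loci)),
    start = GenomicRanges::start(loci) - 1,
    end = GenomicRanges::end(loci),
    n_tissues = as.integer(n_tis),
    tissue = vapply(tis_per_locus,
                    function(x) if (length(x) == 1) x else NA_character_,
                    ""),
    score = as.numeric(score_per_locus),
    nearest_gene = as.character(gene_per_locus),
    stringsAsFactors = FALSE)
  constitutive <- ld[ld$n_tissues == length(tissues), ]
  spec <- ld[ld$n_tissues == 1, ]
  spec_ranked <- list()
  for (t in tissues) {
    st <- spec[spec$tissue == t, ]
    o <- order(-st$score, -(st$end - st$start), st$chrom, st$start)
    if (nrow(st) < top_n) {
      message("tissue ", t, ": only ", nrow(st),
              " specific ACRs (top_n = ", top_n, "); keeping all")
    }
    spec_ranked[[t]] <- utils::head(st[o, ], top_n)
  }
  enrichment <- NULL
  if (!is.null(term_map) && nrow(term_map) > 0) {
    universe <- unique(term_map$gene_id)
    rows <- list()
    for (t in tissues) {
      hits <- intersect(unique(spec_ranked[[t]]$nearest_gene), universe)
      for (term in unique(term_map$term)) {
        set <- unique(term_map$gene_id[term_map$term == term])
        tr <- hypergeom_enrich(length(intersect(hits, set)), length(set),
                               length(hits), length(universe))
        rows[[length(rows) + 1]] <- data.frame(
          tissue = t, term = term, hits = tr$statistic,
          set_size = length(set), fold = tr$effect, p = tr$p_value,
          stringsAsFactors = FALSE)
      }
    }
    enrichment <- do.call(rbind, rows)
    enrichment$adj_p <- bh_adjust(enrichment$p)
  }
  list(constitutive = constitutive, specific = spec_ranked,
       enrichment = enrichment)
}
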