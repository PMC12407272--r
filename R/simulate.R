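#' Simulation configuration
#'
#' Parameters of the synthetic allotetraploid bundle. Defaults describe a
#' two-subgenome genome with ~70% homoeolog expression bias toward
#' subgenome A, a heavier TE load and methylation level on subgenome B,
#' proximal accessible-chromatin regions (ACRs) more often retained on A,
#' progenitor-matching variant genotypes at rate 0.773, 3'UTR-concentrated
#' m6A peaks, and a waterlogging contrast with per-subgenome DEG rates of
#' 0.20 (A) and 0.19 (B) and an m6A peak-loss fraction of 0.16.
#'
#' @param n_chrom_per_subgenome Chromosomes per subgenome.
#' @param genes_per_chrom Ancestral gene slots per chromosome (retained
#'   genes are fewer, by fractionation).
#' @param pair_fraction Fraction of ancestral slots retained in both
#'   subgenomes (homoeolog pairs); the rest become singletons, split
#'   evenly between subgenomes (unbiased fractionation).
#' @param bias_fraction Fraction of pairs with expression bias.
#' @param bias_log2fc Mean |log2FC| of biased pairs (magnitudes drawn
#'   uniformly within +/- 0.75 of this mean).
#' @param bias_toward_A Fraction of biased pairs favouring subgenome A.
#' @param te_density_A,te_density_B TEs per Mb (B > A).
#' @param te_len_mean Mean TE length, bp.
#' @param solo_intact_A,solo_intact_B Target solo:intact LTR ratios.
#' @param meth_te_level Named per-context methylation plateau inside TEs.
#' @param meth_background Named per-context background far from TEs.
#' @param meth_decay_bp Exponential length scale of methylation spreading
#'   from TE edges.
#' @param meth_site_spacing Spacing of simulated cytosine sites, bp.
#' @param meth_coverage Mean read coverage per site.
#' @param acr_prob_A,acr_prob_B Per-gene proximal-ACR probabilities (A > B).
#' @param acr_indel_loss_prob Probability a retained B ACR is destroyed by
#'   an insertion (recorded as an InDel variant).
#' @param acr_constitutive_p Probability an ACR is present in all tissues
#'   (otherwise private to one tissue).
#' @param snp_rate_specific SNPs per kb seeded in subgenome-specific ACRs
#'   (conserved ACRs receive one third of this rate).
#' @param ancestry_match_p Probability a specific-ACR variant's carrier
#'   subgenome genotype matches its progenitor.
#' @param m6a_peak_prob Per-gene m6A peak probability for singletons.
#' @param m6a_share_target Target shared / A-specific / B-specific gene
#'   fractions among methylated pair members.
#' @param m6a_pair_none Fraction of pairs with no m6A peak.
#' @param m6a_utr3_weight Fraction of peaks placed in the 3'UTR.
#' @param m6a_loss_fraction Fraction of control peaks lost under
#'   waterlogging.
#' @param m6a_partial_drop Fraction of retained control peaks whose IP
#'   enrichment drops by \code{m6a_drop_factor} under waterlogging
#'   (the substrate of differential methylation).
#' @param m6a_drop_factor Enrichment drop factor of partially dropped
#'   peaks.
#' @param m6a_input_mean Mean input coverage per transcript window.
#' @param m6a_bin_bp Transcript window size, bp.
#' @param m6a_enrich Peak IP mean as a multiple of the input mean.
#' @param m6a_ip_background IP background mean outside peaks (depleted
#'   relative to input, as IP read mass concentrates in peaks).
#' @param m6a_peak_windows Peak width in transcript windows.
#' @param m6a_repression_coupling Probability that a gene losing its m6A
#'   peak under waterlogging is forced to be an upregulated DEG
#'   (m6A-repression coupling).
#' @param deg_fraction_A,deg_fraction_B Waterlogging DEG rates per
#'   subgenome.
#' @param deg_down_prob Fraction of DEGs that are downregulated.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param replicates Biological replicates per sample group.
#' @param expr_meanlog,expr_sdlog Log-normal baseline expression.
#' @param expr_mu_floor Minimum baseline mean count.
#' @param tissues Tissue panel.
#' @param gene_spacing_bp TSS grid spacing, bp.
#' @param seed Master RNG seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_chrom_per_subgenome = 5, genes_per_chrom = 1250,
                       pair_fraction = 0.6, bias_fraction = 0.70,
                       bias_log2fc = 2, bias_toward_A = 0.8,
                       te_density_A = 240, te_density_B = 280,
                       te_len_mean = 2500,
                       solo_intact_A = 2.7, solo_intact_B = 3.7,
                       meth_te_level = c(CG = 0.90, CHG = 0.65, CHH = 0.18),
                       meth_background = c(CG = 0.25, CHG = 0.08, CHH = 0.04),
                       meth_decay_bp = 400, meth_site_spacing = 200,
                       meth_coverage = 20,
                       acr_prob_A = 0.8, acr_prob_B = 0.5,
                       acr_indel_loss_prob = 0.1, acr_constitutive_p = 0.7,
                       snp_rate_specific = 10, ancestry_match_p = 0.773,
                       m6a_peak_prob = 0.5,
                       m6a_share_target = c(0.82, 0.15, 0.03),
                       m6a_pair_none = 0.05,
                       m6a_utr3_weight = 0.8, m6a_loss_fraction = 0.16,
                       m6a_partial_drop = 0.15, m6a_drop_factor = 3,
                       m6a_input_mean = 10, m6a_enrich = 3,
                       m6a_ip_background = 1, m6a_bin_bp = 50,
                       m6a_peak_windows = 4,
                       m6a_repression_coupling = 0.7,
                       deg_fraction_A = 0.20, deg_fraction_B = 0.19,
                       deg_down_prob = 0.562,
                       nb_dispersion = 0.05, replicates = 3,
                       expr_meanlog = log(150), expr_sdlog = 1,
                       expr_mu_floor = 20,
                       tissues = c("leaf", "root", "stem", "peel", "pulp"),
                       gene_spacing_bp = 5000, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$pair_fraction, cfg$bias_fraction, cfg$bias_toward_A,
             cfg$acr_prob_A, cfg$acr_prob_B, cfg$acr_indel_loss_prob,
             cfg$acr_constitutive_p, cfg$ancestry_match_p,
             cfg$m6a_peak_prob, cfg$m6a_utr3_weight, cfg$m6a_loss_fraction,
             cfg$deg_fraction_A, cfg$deg_fraction_B, cfg$deg_down_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$replicates < 2) stop("at least 2 replicates are required")
  if (cfg$n_chrom_per_subgenome < 1 || cfg$genes_per_chrom < 1) {
    stop("counts must be positive")
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- c("sim_config", "list")
  cfg
}

# deterministic named substream seed below 2^31
substream_seed <- function(seed, name) {
  ints <- utf8ToInt(name)
  as.integer((abs(as.numeric(seed)) * 48271 +
                sum(ints * seq_along(ints)) * 69621) %% 2147483629)
}

GENE_LEN <- 2000L
UTR5_LEN <- 200L
CDS_LEN <- 1500L
UTR3_LEN <- 300L

#' Simulate the genome scaffold
#'
#' Ancestral gene slots, fractionation into pairs and singletons, gene
#' placement on a jittered grid, and perfect anchor hits between retained
#' pair members.
#'
#' @param config A \code{sim_config}.
#' @return List with \code{genome}, \code{genes} (a \code{gene_set}),
#'   \code{slots} (ancestral order), \code{anchors} and \code{pairs_truth}.
#' @export
simulate_genome <- function(config) {
  set.seed(substream_seed(config$seed, "genome"))
  nc <- config$n_chrom_per_subgenome
  ns <- config$genes_per_chrom
  sp <- config$gene_spacing_bp
  if (sp < GENE_LEN + 1200) {
    stop("infeasible geometry: gene spacing too small for gene length")
  }
  chrlen <- 2000 + ns * sp + 2000
  genome <- genome_table(
    chrom = c(sprintf("chr%02dA", seq_len(nc)), sprintf("chr%02dB", seq_len(nc))),
    subgenome = rep(c("A", "B"), each = nc),
    length = rep(chrlen, 2 * nc))

  slot_list <- vector("list", nc)
  for (cc in seq_len(nc)) {
    u <- stats::runif(ns)
    cls <- ifelse(u < config$pair_fraction, "pair",
                  ifelse(u < config$pair_fraction + (1 - config$pair_fraction) / 2,
                         "singleton_A", "singleton_B"))
    slot_list[[cc]] <- data.frame(
      slot = sprintf("s%02d_%05d", cc, seq_len(ns)),
      anc_chrom = cc, slot_order = seq_len(ns), class = cls,
      stringsAsFactors = FALSE)
  }
  slots <- do.call(rbind, slot_list)

  place_genes <- function(sub) {
    keep <- slots$class %in% c("pair", paste0("singleton_", sub))
    s <- slots[keep, ]
    out <- vector("list", nc)
    for (cc in seq_len(nc)) {
      sc <- s[s$anc_chrom == cc, ]
      n <- nrow(sc)
      start <- 2000 + (seq_len(n) - 1) * sp +
        round(stats::runif(n, -500, 500))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      out[[cc]] <- data.frame(
        gene_id = sprintf("Av_%02d%sg%04d", cc, sub, seq_len(n)),
        chrom = sprintf("chr%02d%s", cc, sub), strand = strand,
        start = start, end = start + GENE_LEN, slot = sc$slot,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  gA <- place_genes("A")
  gB <- place_genes("B")
  genes <- rbind(gA, gB)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$subgenome <- subgenome_of(genes$chrom)

  feat <- function(g) {
    plus <- g$strand == "+"
    s <- g$start
    data.frame(
      gene_id = rep(g$gene_id, 4),
      type = rep(c("exon", "five_prime_UTR", "CDS", "three_prime_UTR"),
                 each = nrow(g)),
      start = c(s,
                ifelse(plus, s, s + GENE_LEN - UTR5_LEN),
                ifelse(plus, s + UTR5_LEN, s + UTR3_LEN),
                ifelse(plus, s + UTR5_LEN + CDS_LEN, s)),
      end = c(s + GENE_LEN,
              ifelse(plus, s + UTR5_LEN, s + GENE_LEN),
              ifelse(plus, s + UTR5_LEN + CDS_LEN, s + UTR3_LEN + CDS_LEN),
              ifelse(plus, s + GENE_LEN, s + UTR3_LEN)),
      stringsAsFactors = FALSE)
  }
  features <- feat(genes)
  gs <- structure(list(
    genes = genes[, c("gene_id", "chrom", "strand", "start", "end", "tss",
                      "subgenome")],
    features = features), class = "gene_set")

  slots$gene_a <- gA$gene_id[match(slots$slot, gA$slot)]
  slots$gene_b <- gB$gene_id[match(slots$slot, gB$slot)]

  pairs <- slots[slots$class == "pair", ]
  anchors <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                        similarity = round(stats::runif(nrow(pairs), 0.85, 1), 4),
                        stringsAsFactors = FALSE)
  list(genome = genome, genes = gs, slots = slots, anchors = anchors,
       gene_slot = stats::setNames(genes$slot, genes$gene_id))
}

#' Simulate homoeolog expression counts
#'
#' Negative-binomial counts for the tissue panel plus a waterlogging
#' (CTL/WL) contrast on roots. Biased pairs receive a constant log2 offset
#' (sign per \code{bias_toward_A}); waterlogging DEGs are drawn per
#' subgenome with |log2FC| in [1.5, 3].
#'
#' @param scaffold Output of \code{\link{simulate_genome}}.
#' @param config A \code{sim_config}.
#' @param coupled_up_genes Genes forced to be upregulated DEGs (used for
#'   m6A-repression coupling); may be NULL.
#' @return List with \code{counts} (matrix), \code{samples} (metadata),
#'   \code{lengths}, \code{truth_pairs} and \code{truth_deg}.
#' @export
simulate_expression <- function(scaffold, config, coupled_up_genes = NULL) {
  set.seed(substream_seed(config$seed, "expression"))
  slots <- scaffold$slots
  genes <- scaffold$genes$genes
  nrep <- config$replicates
  tissues <- config$tissues

  # baseline mean per ancestral slot, shared by both pair members
  mu0 <- pmax(stats::rlnorm(nrow(slots), config$expr_meanlog,
                            config$expr_sdlog), config$expr_mu_floor)
  names(mu0) <- slots$slot
  # per-slot tissue modulation, shared within a pair so that unbiased
  # pairs are truly null in every tissue
  tis_fac <- matrix(stats::rlnorm(nrow(slots) * length(tissues), 0, 0.5),
                    nrow = nrow(slots),
                    dimnames = list(slots$slot, tissues))

  is_pair <- slots$class == "pair"
  biased <- is_pair & stats::runif(nrow(slots)) < config$bias_fraction
  toward_a <- stats::runif(nrow(slots)) < config$bias_toward_A
  mag <- stats::runif(nrow(slots), config$bias_log2fc - 0.75,
                      config$bias_log2fc + 0.75)
  lfc_ab <- ifelse(biased, ifelse(toward_a, mag, -mag), 0)  # log2(A/B)

  truth_pairs <- data.frame(
    slot = slots$slot, gene_a = slots$gene_a, gene_b = slots$gene_b,
    class = slots$class,
    bias_class = ifelse(!is_pair, NA_character_,
                        ifelse(!biased, "unbiased",
                               ifelse(toward_a, "A", "B"))),
    bias_log2fc = ifelse(is_pair, lfc_ab, NA_real_),
    stringsAsFactors = FALSE)

  # per-gene means: the favoured member is upregulated by the full
  # offset, the other keeps the baseline (dominance as gain, keeping
  # every gene at or above the baseline floor)
  genes$slot <- unname(scaffold$gene_slot[genes$gene_id])
  si <- match(genes$slot, slots$slot)
  up <- ifelse(genes$subgenome == "A", pmax(lfc_ab[si], 0),
               pmax(-lfc_ab[si], 0))
  mu_gene <- mu0[si] * 2^up

  # waterlogging DEG truth; coupled genes (upregulated, m6A-linked) are
  # drawn inside the per-subgenome DEG budget so the rate stays on target
  frac <- ifelse(genes$subgenome == "A", config$deg_fraction_A,
                 config$deg_fraction_B)
  coupled <- genes$gene_id %in% coupled_up_genes
  p_rest <- numeric(nrow(genes))
  for (s in c("A", "B")) {
    sel <- genes$subgenome == s
    target <- if (s == "A") config$deg_fraction_A else config$deg_fraction_B
    pc <- mean(coupled[sel])
    p_rest[sel] <- max(0, (target - pc) / (1 - pc))
  }
  is_deg <- coupled | stats::runif(nrow(genes)) < p_rest
  down <- stats::runif(nrow(genes)) < config$deg_down_prob
  down[coupled] <- FALSE
  wl_mag <- stats::runif(nrow(genes), 1.5, 3)
  lfc_wl <- ifelse(is_deg, ifelse(down, -wl_mag, wl_mag), 0)
  truth_deg <- data.frame(gene_id = genes$gene_id,
                          subgenome = genes$subgenome,
                          is_deg = is_deg, lfc_wl = lfc_wl,
                          stringsAsFactors = FALSE)

  sample_names <- c(
    as.vector(t(outer(tissues, seq_len(nrep),
                      function(t, r) sprintf("%s_%d", t, r)))),
    sprintf("root_CTL_%d", seq_len(nrep)),
    sprintf("root_WL_%d", seq_len(nrep)))
  samples <- data.frame(
    sample = sample_names,
    tissue = c(rep(tissues, each = nrep), rep("root", 2 * nrep)),
    condition = c(rep("", length(tissues) * nrep),
                  rep(c("CTL", "WL"), each = nrep)),
    replicate = c(rep(seq_len(nrep), length(tissues)),
                  rep(seq_len(nrep), 2)),
    stringsAsFactors = FALSE)
  depth <- stats::rlnorm(nrow(samples), 0, 0.1)

  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, nrow = nrow(genes), ncol = nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    tis <- samples$tissue[j]
    mu_j <- mu_gene * tis_fac[si, tis] * depth[j]
    if (samples$condition[j] == "WL") mu_j <- mu_j * 2^lfc_wl
    counts[, j] <- stats::rnbinom(nrow(genes), mu = mu_j, size = size)
  }
  lengths <- stats::setNames(rep(GENE_LEN, nrow(genes)), genes$gene_id)
  list(counts = counts, samples = samples, lengths = lengths,
       truth_pairs = truth_pairs, truth_deg = truth_deg)
}

#' Simulate transposable elements and LTR records
#'
#' TEs placed by a Poisson process with subgenome-specific density;
#' LTR retrotransposons are marked solo or intact so that the expected
#' solo:intact ratio matches the configured per-subgenome targets, with
#' per-site LTR divergence on intact elements.
#'
#' @inheritParams simulate_expression
#' @return List with \code{tes} (BED-style data.frame) and \code{ltrs}.
#' @export
simulate_tes <- function(scaffold, config) {
  set.seed(substream_seed(config$seed, "te"))
  genome <- scaffold$genome
  out <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    dens <- if (genome$subgenome[i] == "A") config$te_density_A else
      config$te_density_B
    n <- stats::rpois(1, dens * genome$length[i] / 1e6)
    len <- 300 + round(stats::rexp(n, 1 / (config$te_len_mean - 300)))
    start <- floor(stats::runif(n, 0, genome$length[i] - len))
    fam <- sample(c("Copia", "Gypsy", "other"), n, replace = TRUE,
                  prob = c(0.4, 0.35, 0.25))
    out[[i]] <- data.frame(chrom = genome$chrom[i], start = start,
                           end = start + len,
                           name = sprintf("TE_%s_%05d", genome$chrom[i],
                                          seq_len(n)),
                           score = 0, strand = "+", family = fam,
                           subgenome = genome$subgenome[i],
                           stringsAsFactors = FALSE)
  }
  tes <- do.call(rbind, out)
  tes <- tes[order(tes$chrom, tes$start), ]
  rownames(tes) <- NULL

  ltr <- tes[tes$family %in% c("Copia", "Gypsy"), ]
  r <- ifelse(ltr$subgenome == "A", config$solo_intact_A,
              config$solo_intact_B)
  solo <- stats::runif(nrow(ltr)) < r / (1 + r)
  ltrs <- data.frame(id = ltr$name, subgenome = ltr$subgenome,
                     kind = ifelse(solo, "solo", "intact"),
                     ltr_divergence = ifelse(solo, NA_real_,
                                             abs(stats::rnorm(nrow(ltr),
                                                              0.07, 0.02))),
                     family = ltr$family, stringsAsFactors = FALSE)
  list(tes = tes, ltrs = ltrs)
}

#' Simulate a bisulfite methylome shaped by TE spreading
#'
#' Cytosine sites on a regular grid; the mean methylation level of a site
#' at distance d from the nearest TE edge is
#' background + (plateau - background) * exp(-d / meth_decay_bp), per
#' context, with binomial sampling at Poisson coverage.
#'
#' @param tes TE intervals (data.frame chrom/start/end).
#' @inheritParams simulate_expression
#' @return Methylation data.frame (chrom, pos, context, mc_count,
#'   total_count, level).
#' @export
simulate_methylome <- function(tes, scaffold, config) {
  set.seed(substream_seed(config$seed, "methylome"))
  genome <- scaffold$genome
  pos_l <- lapply(seq_len(nrow(genome)), function(i) {
    p <- seq(100, genome$length[i] - 100, by = config$meth_site_spacing)
    data.frame(chrom = genome$chrom[i], pos = p, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, pos_l)
  ctx <- sample(c("CG", "CHG", "CHH"), nrow(sites), replace = TRUE,
                prob = c(0.25, 0.25, 0.5))
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1,
                                                     sites$pos + 1))
  te_gr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(tes$start + 1, tes$end))
  d <- rep(Inf, nrow(sites))
  hits <- GenomicRanges::distanceToNearest(site_gr, te_gr)
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  plat <- config$meth_te_level[ctx]
  bg <- config$meth_background[ctx]
  level <- bg + (plat - bg) * exp(-d / config$meth_decay_bp)
  cov <- stats::rpois(nrow(sites), config$meth_coverage)
  mc <- stats::rbinom(nrow(sites), cov, level)
  data.frame(chrom = sites$chrom, pos = sites$pos, context = ctx,
             mc_count = mc, total_count = cov,
             level = ifelse(cov > 0, mc / cov, NA_real_),
             stringsAsFactors = FALSE)
}

#' Simulate ACRs, their tissue presence, and variants
#'
#' Each gene carries a proximal ACR with subgenome-specific probability;
#' pair members share the ACR's TSS offset so that a retained pair is a
#' conserved ACR. Retained B copies are additionally destroyed with
#' \code{acr_indel_loss_prob}, recorded as a 126-bp insertion variant.
#' Subgenome-specific ACR regions are seeded with SNPs whose carrier
#' progenitor genotype matches the carrier subgenome with probability
#' \code{ancestry_match_p}; conserved ACRs receive SNPs at one third of
#' the specific rate.
#'
#' @inheritParams simulate_expression
#' @return List with \code{acrs} (long format incl. tissue), \code{variants},
#'   \code{truth_acrs} and \code{term_map}.
#' @export
simulate_acrs_and_variants <- function(scaffold, config) {
  set.seed(substream_seed(config$seed, "acr"))
  slots <- scaffold$slots
  genes <- scaffold$genes$genes
  tissues <- config$tissues
  rownames(genes) <- genes$gene_id

  width <- 300L
  # per-slot shared geometry and tissue presence
  off <- round(stats::runif(nrow(slots), 150, 800))   # TSS gap, bp
  constit <- stats::runif(nrow(slots)) < config$acr_constitutive_p
  private_tis <- sample(tissues, nrow(slots), replace = TRUE)
  score <- round(stats::rgamma(nrow(slots), shape = 2, scale = 5) + 1, 3)

  has_a <- !is.na(slots$gene_a) & stats::runif(nrow(slots)) < config$acr_prob_A
  has_b <- !is.na(slots$gene_b) & stats::runif(nrow(slots)) < config$acr_prob_B
  destroyed_b <- has_b & stats::runif(nrow(slots)) < config$acr_indel_loss_prob

  mk_acr <- function(gene_ids, keep, sub) {
    idx <- which(keep)
    g <- genes[gene_ids[idx], ]
    plus <- g$strand == "+"
    start <- ifelse(plus, g$tss - off[idx] - width, g$tss + off[idx] + 1)
    end <- start + width
    data.frame(slot_i = idx, acr_id = paste0(g$gene_id, "_acr"),
               gene_id = g$gene_id, chrom = g$chrom,
               start = start, end = end, score = score[idx],
               subgenome = sub,
               constit = constit[idx], private_tis = private_tis[idx],
               stringsAsFactors = FALSE)
  }
  acr_a <- mk_acr(slots$gene_a, has_a, "A")
  acr_b_all <- mk_acr(slots$gene_b, has_b, "B")
  acr_b <- acr_b_all[!destroyed_b[acr_b_all$slot_i], ]
  acr_b_lost <- acr_b_all[destroyed_b[acr_b_all$slot_i], ]
  acr <- rbind(acr_a, acr_b)

  pair_slot <- slots$class == "pair"
  kept_b <- has_b & !destroyed_b
  truth_class <- function(sub, i) {
    if (sub == "A") {
      if (!pair_slot[i]) return("specific-noanchor")
      if (kept_b[i]) "conserved" else "A-specific"
    } else {
      if (!pair_slot[i]) return("specific-noanchor")
      if (has_a[i]) "conserved" else "B-specific"
    }
  }
  acr$truth <- vapply(seq_len(nrow(acr)),
                      function(k) truth_class(acr$subgenome[k], acr$slot_i[k]),
                      character(1))

  # long format with tissue presence (shared within a slot)
  expand <- function(d) {
    tis_l <- lapply(seq_len(nrow(d)), function(i) {
      if (d$constit[i]) tissues else d$private_tis[i]
    })
    n <- lengths(tis_l)
    out <- d[rep(seq_len(nrow(d)), n), ]
    out$tissue <- unlist(tis_l)
    out
  }
  acrs_long <- expand(acr)
  acrs_long <- acrs_long[, c("chrom", "start", "end", "acr_id", "score",
                             "tissue", "subgenome", "gene_id")]
  rownames(acrs_long) <- NULL

  truth_acrs <- acr[, c("acr_id", "gene_id", "chrom", "start", "end",
                        "score", "subgenome", "truth", "constit",
                        "private_tis")]
  rownames(truth_acrs) <- NULL

  # variants
  spec <- acr[acr$truth != "conserved", ]
  cons <- acr[acr$truth == "conserved", ]
  bases <- c("A", "C", "G", "T")
  mk_snps <- function(d, rate, specific) {
    n_per <- stats::rpois(nrow(d), rate * (d$end - d$start) / 1000)
    idx <- rep(seq_len(nrow(d)), n_per)
    if (length(idx) == 0) return(NULL)
    pos <- floor(stats::runif(length(idx), d$start[idx], d$end[idx])) + 1
    ref <- sample(bases, length(idx), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "",
                  USE.NAMES = FALSE)
    carrier <- d$subgenome[idx]
    match_p <- stats::runif(length(idx)) < config$ancestry_match_p
    miss <- stats::runif(length(idx)) < 0.02
    v <- data.frame(chrom = d$chrom[idx], pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
    if (specific) {
      v$subA <- ifelse(carrier == "A", "alt", "ref")
      v$subB <- ifelse(carrier == "B", "alt", "ref")
      carr_allele <- "alt"
      v$progA <- ifelse(carrier == "A",
                        ifelse(match_p, carr_allele, "ref"), "ref")
      v$progB <- ifelse(carrier == "B",
                        ifelse(match_p, carr_allele, "ref"), "ref")
      v$progA[miss & carrier == "A"] <- NA
      v$progB[miss & carrier == "B"] <- NA
    } else {
      v$subA <- "alt"; v$subB <- "alt"
      v$progA <- ifelse(match_p, "alt", "ref")
      v$progB <- ifelse(match_p, "alt", "ref")
    }
    v
  }
  v_spec <- mk_snps(spec, config$snp_rate_specific, TRUE)
  v_cons <- mk_snps(cons, config$snp_rate_specific / 3, FALSE)
  # the recorded insertion that destroyed each lost B ACR: the surviving
  # A copy is the specific-ACR carrier; subB carries the insertion allele
  v_ins <- NULL
  if (nrow(acr_b_lost) > 0) {
    ins_seq <- vapply(seq_len(nrow(acr_b_lost)), function(k) {
      paste(sample(bases, 126, replace = TRUE), collapse = "")
    }, "")
    match_p <- stats::runif(nrow(acr_b_lost)) < config$ancestry_match_p
    v_ins <- data.frame(
      chrom = acr_b_lost$chrom, pos = acr_b_lost$start + 1,
      ref = substr(ins_seq, 1, 1),
      alt = paste0(substr(ins_seq, 1, 1), ins_seq),
      subA = "ref", subB = "alt",
      progA = "ref", progB = ifelse(match_p, "alt", "ref"),
      stringsAsFactors = FALSE)
  }
  variants <- rbind(v_spec, v_cons, v_ins)
  variants$type <- ifelse(nchar(variants$ref) == 1 &
                            nchar(variants$alt) == 1, "SNP", "InDel")
  variants <- variants[order(variants$chrom, variants$pos),
                       c("chrom", "pos", "ref", "alt", "type",
                         "subA", "subB", "progA", "progB")]
  rownames(variants) <- NULL

  # term map with tissue-linked terms planted on private-ACR genes
  bg_terms <- sprintf("TERM_bg%d", 1:5)
  specific_private <- acr[!acr$constit, ]
  planted <- specific_private[stats::runif(nrow(specific_private)) < 0.6, ]
  tm1 <- if (nrow(planted) > 0) {
    data.frame(gene_id = planted$gene_id,
               term = paste0("TERM_", planted$private_tis),
               stringsAsFactors = FALSE)
  } else NULL
  draws <- which(matrix(stats::runif(nrow(genes) * 5), ncol = 5) < 0.05,
                 arr.ind = TRUE)
  tm2 <- data.frame(gene_id = genes$gene_id[draws[, 1]],
                    term = bg_terms[draws[, 2]], stringsAsFactors = FALSE)
  term_map <- unique(rbind(tm1, tm2))
  term_map <- term_map[order(term_map$gene_id, term_map$term), ]
  rownames(term_map) <- NULL

  list(acrs = acrs_long, variants = variants, truth_acrs = truth_acrs,
       term_map = term_map)
}

#' Simulate m6A peak truth (placement and waterlogging fate)
#'
#' Pairs receive correlated peak status so that the shared/A-specific/
#' B-specific gene fractions among methylated pair members hit
#' \code{m6a_share_target}; singletons use \code{m6a_peak_prob}. Peaks are
#' placed in the 3'UTR with weight \code{m6a_utr3_weight} (remainder CDS
#' then 5'UTR) and span two 50-bp transcript windows; a configured
#' fraction of control peaks lose IP enrichment under waterlogging.
#'
#' @inheritParams simulate_expression
#' @return data.frame gene_id, tx_start, tx_end, feature, lost_in_wl.
#' @export
simulate_m6a_truth <- function(scaffold, config) {
  set.seed(substream_seed(config$seed, "m6a_truth"))
  slots <- scaffold$slots
  genes <- scaffold$genes$genes

  s <- config$m6a_share_target
  t_norm <- (1 - config$m6a_pair_none) / (s[1] / 2 + s[2] + s[3])
  q <- c(both = s[1] / 2 * t_norm, A = s[2] * t_norm, B = s[3] * t_norm)
  pair_i <- which(slots$class == "pair")
  cat_draw <- sample(c("both", "A", "B", "none"), length(pair_i),
                     replace = TRUE, prob = c(q, 1 - sum(q)))
  peak_gene <- character(0)
  peak_gene <- c(peak_gene,
                 slots$gene_a[pair_i[cat_draw %in% c("both", "A")]],
                 slots$gene_b[pair_i[cat_draw %in% c("both", "B")]])
  singles <- genes$gene_id[!(genes$gene_id %in%
                               c(slots$gene_a[pair_i], slots$gene_b[pair_i]))]
  singles <- singles[stats::runif(length(singles)) < config$m6a_peak_prob]
  peak_gene <- sort(c(peak_gene, singles))

  n <- length(peak_gene)
  u <- stats::runif(n)
  w3 <- config$m6a_utr3_weight
  feature <- ifelse(u < w3, "3'UTR",
                    ifelse(u < w3 + (1 - w3) * 0.75, "CDS", "5'UTR"))
  bin <- config$m6a_bin_bp
  nwin <- GENE_LEN %/% bin
  w <- config$m6a_peak_windows
  # window index ranges per feature (1-based windows, tx coords); the
  # peak spans w consecutive windows fully inside its feature
  first_win <- integer(n)
  u5w <- UTR5_LEN %/% bin; cdw <- CDS_LEN %/% bin
  pick <- function(lo, span, k) {
    lo + sample(seq_len(max(span - w + 1, 1)), k, replace = TRUE) - 1L
  }
  first_win[feature == "5'UTR"] <- pick(1L, u5w, sum(feature == "5'UTR"))
  first_win[feature == "CDS"] <- pick(u5w + 1L, cdw, sum(feature == "CDS"))
  first_win[feature == "3'UTR"] <- pick(u5w + cdw + 1L, nwin - u5w - cdw,
                                        sum(feature == "3'UTR"))
  lost <- stats::runif(n) < config$m6a_loss_fraction
  partial <- !lost & stats::runif(n) < config$m6a_partial_drop
  data.frame(gene_id = peak_gene, win_start = first_win,
             win_end = first_win + w - 1L,
             tx_start = (first_win - 1L) * bin,
             tx_end = (first_win + w - 1L) * bin,
             feature = feature, lost_in_wl = lost,
             partial_drop = partial,
             stringsAsFactors = FALSE)
}

#' Simulate windowed m6A IP/input counts
#'
#' Poisson input background everywhere; IP counts inflated by
#' \code{m6a_enrich} inside true peak windows (control always; waterlogged
#' unless the peak is lost).
#'
#' @param truth Output of \code{\link{simulate_m6a_truth}}.
#' @inheritParams simulate_expression
#' @return data.frame gene_id, win_index, start, end, ip, input, condition.
#' @export
simulate_m6a_counts <- function(truth, scaffold, config) {
  set.seed(substream_seed(config$seed, "m6a_counts"))
  genes <- scaffold$genes$genes
  bin <- config$m6a_bin_bp
  nwin <- GENE_LEN %/% bin
  base <- expand.grid(win_index = seq_len(nwin), gene_id = genes$gene_id,
                      stringsAsFactors = FALSE)[, c("gene_id", "win_index")]
  base$start <- (base$win_index - 1L) * bin
  base$end <- base$win_index * bin
  w <- config$m6a_peak_windows
  gi <- match(base$gene_id, genes$gene_id)
  ti <- match(truth$gene_id, genes$gene_id)
  key <- gi * (nwin + w + 1) + base$win_index
  peak_keys <- as.vector(outer(ti * (nwin + w + 1) + truth$win_start,
                               seq_len(w) - 1L, "+"))
  in_peak <- key %in% peak_keys
  lost_genes <- truth$gene_id[truth$lost_in_wl]
  partial_genes <- truth$gene_id[truth$partial_drop]
  in_peak_wl <- in_peak & !(base$gene_id %in% lost_genes)
  partial_wl <- in_peak_wl & base$gene_id %in% partial_genes

  lam <- config$m6a_input_mean
  bg <- config$m6a_ip_background
  peak_mu <- lam * config$m6a_enrich
  out <- vector("list", 2)
  for (k in 1:2) {
    cond <- c("CTL", "WL")[k]
    d <- base
    mu_ip <- if (cond == "CTL") {
      ifelse(in_peak, peak_mu, bg)
    } else {
      ifelse(partial_wl, peak_mu / config$m6a_drop_factor,
             ifelse(in_peak_wl, peak_mu, bg))
    }
    d$ip <- stats::rpois(nrow(d), mu_ip)
    d$input <- stats::rpois(nrow(d), lam)
    d$condition <- cond
    out[[k]] <- d
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic allotetraploid dataset bundle
#'
#' Composes all simulators under one master seed with named substreams,
#' optionally writing every table to \code{outdir} in the formats the
#' pipeline reads (GFF3, TSV, VCF, YAML) plus truth tables.
#'
#' @param config A \code{sim_config}.
#' @param outdir Optional output directory (created if needed).
#' @return A \code{dataset_bundle}: list of in-memory tables (and file
#'   paths when \code{outdir} is given).
#' @export
generate_dataset <- function(config = sim_config(), outdir = NULL) {
  scaffold <- simulate_genome(config)
  m6a_truth <- simulate_m6a_truth(scaffold, config)
  # m6A-repression coupling uses its own substream
  set.seed(substream_seed(config$seed, "coupling"))
  dropped <- m6a_truth$gene_id[m6a_truth$lost_in_wl | m6a_truth$partial_drop]
  coupled <- dropped[stats::runif(length(dropped)) <
                       config$m6a_repression_coupling]
  expr <- simulate_expression(scaffold, config, coupled_up_genes = coupled)
  te <- simulate_tes(scaffold, config)
  meth <- simulate_methylome(te$tes, scaffold, config)
  acrv <- simulate_acrs_and_variants(scaffold, config)
  m6a_windows <- simulate_m6a_counts(m6a_truth, scaffold, config)

  bundle <- list(
    config = config, genome = scaffold$genome, genes = scaffold$genes,
    slots = scaffold$slots, anchors = scaffold$anchors,
    counts = expr$counts, samples = expr$samples, lengths = expr$lengths,
    tes = te$tes, ltrs = te$ltrs, methylation = meth,
    acrs = acrv$acrs, variants = acrv$variants, term_map = acrv$term_map,
    m6a_windows = m6a_windows,
    truth = list(pairs = expr$truth_pairs, deg = expr$truth_deg,
                 acrs = acrv$truth_acrs, m6a = m6a_truth,
                 coupled_genes = coupled))
  class(bundle) <- c("dataset_bundle", "list")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(outdir, f)
    write_tsv(scaffold$genome, fp("genome.tsv"))
    write_gff3(scaffold$genes, fp("genes.gff3"))
    anc <- scaffold$slots[, c("slot", "anc_chrom", "slot_order",
                              "gene_a", "gene_b")]
    write_tsv(anc, fp("ancestral_order.tsv"))
    write_tsv(scaffold$anchors, fp("anchors.tsv"))
    write_counts(expr$counts, fp("counts.tsv"))
    write_tsv(expr$samples, fp("samples.tsv"))
    write_tsv(data.frame(gene_id = names(expr$lengths),
                         length = unname(expr$lengths)),
              fp("gene_lengths.tsv"))
    write_bed(te$tes, fp("tes.bed"))
    write_tsv(te$ltrs, fp("ltrs.tsv"))
    write_methylation(meth, fp("methylation.tsv"))
    write_tsv(acrv$acrs, fp("acrs.tsv"))
    write_variants(acrv$variants, fp("variants.vcf"))
    write_tsv(acrv$term_map, fp("term_map.tsv"))
    data.table::fwrite(m6a_windows, fp("m6a_windows.tsv"), sep = "\t",
                       quote = FALSE)
    write_tsv(expr$truth_pairs, fp("truth_pairs.tsv"))
    write_tsv(expr$truth_deg, fp("truth_deg.tsv"))
    write_tsv(acrv$truth_acrs, fp("truth_acrs.tsv"))
    write_tsv(m6a_truth, fp("truth_m6a.tsv"))
    cfg <- config
    cfg$meth_te_level <- as.list(cfg$meth_te_level)
    cfg$meth_background <- as.list(cfg$meth_background)
    yaml::write_yaml(unclass(cfg), fp("sim_config.yaml"))
    bundle$dir <- outdir
  }
  bundle
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("synthetic allotetraploid dataset bundle\n")
  cat(sprintf("  %d genes, %d pairs, %d TEs, %d methylation sites\n",
              nrow(x$genes$genes), sum(x$slots$class == "pair"),
              nrow(x$tes), nrow(x$methylation)))
  cat(sprintf("  %d ACR records, %d variants, %d m6A windows, seed %d\n",
              nrow(x$acrs), nrow(x$variants), nrow(x$m6a_windows),
              x$config$seed))
  invisible(x)
}
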