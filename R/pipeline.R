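#' Run the full subgenome-dominance pipeline on a dataset directory
#'
#' Executes the homoeology, expression, methylome, chromatin and m6a
#' stages over a bundle directory (as written by
#' \code{\link{generate_dataset}}, or assembled from real data in the
#' same formats), writing one TSV per result plus a key-value
#' \code{summary.tsv}. Outputs are a pure function of (inputs, config,
#' seed); any stage failure aborts with the stage name and cause.
#'
#' @param indir Input bundle directory.
#' @param outdir Output directory (created).
#' @param config An \code{\link{analysis_config}}.
#' @param stages Stages to run (subset, in pipeline order).
#' @return Invisibly, a list of all stage results including the summary.
#' @export
run_pipeline <- function(indir, outdir,
                         config = analysis_config(),
                         stages = c("homoeology", "expression", "methylome",
                                    "chromatin", "m6a")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  need <- function(f, stage) {
    p <- file.path(indir, f)
    if (!file.exists(p)) {
      stop("stage '", stage, "' failed: missing input file ", f)
    }
    p
  }
  run_stage <- function(stage, fun) {
    out <- tryCatch(fun(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    gc(verbose = FALSE)   # stages handle large tables; keep peaks bounded
    out
  }
  res <- list()
  summ <- list()
  add <- function(metric, value) {
    summ[[length(summ) + 1]] <<- data.frame(metric = metric,
                                            value = as.numeric(value))
  }
  genome <- genome_table(
    chrom = read_tsv(need("genome.tsv", "core"))$chrom,
    subgenome = read_tsv(file.path(indir, "genome.tsv"))$subgenome,
    length = read_tsv(file.path(indir, "genome.tsv"))$length)
  gs <- read_gff3(need("genes.gff3", "core"), genome = genome)
  subg <- stats::setNames(gs$genes$subgenome, gs$genes$gene_id)

  map <- NULL
  if ("homoeology" %in% stages) {
    res$homoeology <- run_stage("homoeology", function() {
      anchors <- read_tsv(need("anchors.tsv", "homoeology"))
      ao <- read_tsv(need("ancestral_order.tsv", "homoeology"))
      m <- pair_homoeologs(gs, anchors)
      prof <- fractionation_profile(ao, window_genes = config$window_genes)
      bal <- retention_balance_test(prof)
      write_tsv(m$pairs, file.path(outdir, "homoeolog_pairs.tsv"))
      write_tsv(data.frame(
        gene_id = c(m$singletons_a, m$singletons_b),
        subgenome = c(rep("A", length(m$singletons_a)),
                      rep("B", length(m$singletons_b)))),
        file.path(outdir, "singletons.tsv"))
      write_tsv(prof, file.path(outdir, "fractionation_profile.tsv"))
      list(map = m, profile = prof, balance = bal)
    })
    map <- res$homoeology$map
    add("n_pairs", nrow(map$pairs))
    add("retention_balance_p", res$homoeology$balance$p_value)
  }

  de <- NULL
  if ("expression" %in% stages) {
    res$expression <- run_stage("expression", function() {
      counts <- read_counts(need("counts.tsv", "expression"))
      samples <- read_tsv(need("samples.tsv", "expression"),
                          colClasses = c(condition = "character"))
      samples$condition[is.na(samples$condition)] <- ""
      lens <- read_tsv(need("gene_lengths.tsv", "expression"))
      lengths <- stats::setNames(lens$length, lens$gene_id)
      tpm <- compute_tpm(counts, lengths)
      expr <- filter_expressed(tpm, config$tpm_min, subgenome = subg)
      bias <- if (!is.null(map)) {
        homoeolog_bias(counts, samples, map,
                       bias_adj_p = config$bias_adj_p)
      } else NULL
      sing <- if (!is.null(map) && length(map$singletons_a) > 0 &&
                  length(map$singletons_b) > 0) {
        singleton_comparison(tpm, map)
      } else NULL
      ctl <- samples$sample[samples$condition == "CTL"]
      wl <- samples$sample[samples$condition == "WL"]
      de_res <- NULL
      if (length(ctl) >= 2 && length(wl) >= 2) {
        de_res <- nb_differential(counts, ctl, wl, de_fc = config$de_fc,
                                  de_fdr = config$de_fdr)
        write_tsv(de_res, file.path(outdir, "deg.tsv"))
        write_tsv(subgenome_deg_summary(de_res, subg),
                  file.path(outdir, "subgenome_summary.tsv"))
      }
      write_tsv(data.frame(gene_id = rownames(tpm), round(tpm, 4),
                           check.names = FALSE),
                file.path(outdir, "tpm.tsv"))
      if (!is.null(bias)) {
        write_tsv(bias$calls, file.path(outdir, "bias_calls.tsv"))
      }
      list(tpm = tpm, expressed = expr, bias = bias, singleton = sing,
           de = de_res)
    })
    de <- res$expression$de
    ex <- res$expression$expressed$summary
    if (!is.null(ex)) {
      for (i in seq_len(nrow(ex))) {
        add(paste0("expressed_genes_", ex$subgenome[i]), ex$expressed[i])
      }
    }
    if (!is.null(res$expression$bias)) {
      add("biased_pair_fraction",
          res$expression$bias$summary$biased_fraction)
    }
    if (!is.null(res$expression$singleton)) {
      add("singleton_comparison_p", res$expression$singleton$p_value)
    }
    if (!is.null(de)) {
      ds <- subgenome_deg_summary(de, subg)
      for (i in seq_len(nrow(ds))) {
        add(paste0("deg_rate_", ds$subgenome[i]), ds$rate[i])
        add(paste0("deg_total_", ds$subgenome[i]), ds$total[i])
      }
    }
  }

  if ("methylome" %in% stages) {
    res$methylome <- run_stage("methylome", function() {
      tes <- read_bed(need("tes.bed", "methylome"))
      meth <- read_methylation(need("methylation.tsv", "methylome"))
      tc <- te_content(tes, genome)
      dist <- nearest_te_distance(gs, tes)
      gm <- global_methylation(meth, genome)
      prof_te <- metaprofile(meth, tes, flank_bp = config$flank_bp)
      prof_gene <- metaprofile(meth, gs$genes, flank_bp = config$flank_bp)
      si <- NULL
      lp <- file.path(indir, "ltrs.tsv")
      if (file.exists(lp)) si <- solo_intact_ratio(read_tsv(lp))
      write_tsv(tc, file.path(outdir, "te_content.tsv"))
      write_tsv(dist$medians, file.path(outdir, "te_distance.tsv"))
      write_tsv(gm, file.path(outdir, "global_methylation.tsv"))
      write_tsv(prof_te, file.path(outdir, "metaprofile_te.tsv"))
      write_tsv(prof_gene, file.path(outdir, "metaprofile_gene.tsv"))
      if (!is.null(si)) write_tsv(si, file.path(outdir, "solo_intact.tsv"))
      list(te_content = tc, te_distance = dist, global_meth = gm,
           metaprofile_te = prof_te, metaprofile_gene = prof_gene,
           solo_intact = si)
    })
    tc <- res$methylome$te_content
    for (i in seq_len(nrow(tc))) {
      add(paste0("te_fraction_", tc$subgenome[i]), tc$fraction[i])
    }
    gm <- res$methylome$global_meth
    for (i in seq_len(nrow(gm))) {
      add(sprintf("meth_%s_%s", gm$context[i], gm$subgenome[i]),
          gm$level[i])
    }
  }

  if ("chromatin" %in% stages) {
    res$chromatin <- run_stage("chromatin", function() {
      acrs <- read_tsv(need("acrs.tsv", "chromatin"))
      variants <- read_variants(need("variants.vcf", "chromatin"))
      tmp <- file.path(indir, "term_map.tsv")
      term_map <- if (file.exists(tmp)) read_tsv(tmp) else NULL
      cls <- classify_position(acrs, gs, proximal_bp = config$proximal_bp)
      rates <- acr_per_gene(cls, gs)
      cons <- if (!is.null(map)) {
        classify_conservation(cls, gs, map)
      } else NULL
      out <- list(classes = cls, rates = rates, conservation = cons)
      if (!is.null(cons)) {
        dv <- acr_variant_density(cons, variants)
        anc <- ancestry_attribution(variants, cons)
        out$divergence <- dv
        out$ancestry <- anc
        write_tsv(cons, file.path(outdir, "acr_classified.tsv"))
        write_tsv(dv$per_acr, file.path(outdir, "acr_divergence.tsv"))
        write_tsv(data.frame(matches = anc$matches,
                             informative = anc$informative,
                             fraction = anc$fraction),
                  file.path(outdir, "ancestry.tsv"))
      } else {
        write_tsv(cls, file.path(outdir, "acr_classified.tsv"))
      }
      ts <- tissue_specific_acrs(cls, term_map = term_map)
      spec_all <- do.call(rbind, ts$specific)
      write_tsv(spec_all, file.path(outdir, "tissue_specific.tsv"))
      if (!is.null(ts$enrichment)) {
        write_tsv(ts$enrichment, file.path(outdir, "acr_enrichment.tsv"))
      }
      out$tissue_specific <- ts
      out
    })
    rt <- res$chromatin$rates$rates
    for (i in seq_len(nrow(rt))) {
      add(paste0("acr_per_gene_", rt$subgenome[i]), rt$rate[i])
    }
    if (!is.null(res$chromatin$ancestry)) {
      add("ancestry_match_fraction", res$chromatin$ancestry$fraction)
    }
  }

  if ("m6a" %in% stages) {
    res$m6a <- run_stage("m6a", function() {
      windows <- as.data.frame(
        data.table::fread(need("m6a_windows.tsv", "m6a"), sep = "\t"))
      pk <- call_peaks_by_condition(windows, ratio_min = config$m6a_ratio,
                                    p_max = config$m6a_p)
      ann <- lapply(pk, annotate_feature, gs = gs)
      peaks_ctl <- ann$CTL$peaks
      peaks_wl <- ann$WL$peaks
      cmp <- condition_compare(peaks_ctl, peaks_wl, subg)
      shr <- if (!is.null(map)) homoeolog_sharing(peaks_ctl, map) else NULL
      dm <- differential_m6a(windows, peaks_ctl, peaks_wl,
                             fdr = config$m6a_diff_fdr,
                             min_dlfc = config$m6a_diff_lfc)
      integ <- if (!is.null(de)) integrate_de_m6a(dm, de) else NULL
      write_tsv(peaks_ctl, file.path(outdir, "m6a_peaks_ctl.tsv"))
      write_tsv(peaks_wl, file.path(outdir, "m6a_peaks_wl.tsv"))
      write_tsv(cmp$counts, file.path(outdir, "m6a_condition.tsv"))
      if (!is.null(shr)) {
        write_tsv(shr, file.path(outdir, "m6a_sharing.tsv"))
      }
      write_tsv(dm, file.path(outdir, "m6a_differential.tsv"))
      if (!is.null(integ)) {
        tab <- as.data.frame(integ$table)
        write_tsv(tab, file.path(outdir, "de_m6a_integration.tsv"))
      }
      list(peaks_ctl = peaks_ctl, peaks_wl = peaks_wl,
           enrichment = ann$CTL$enrichment, compare = cmp, sharing = shr,
           differential = dm, integration = integ)
    })
    cc <- res$m6a$compare$counts
    add("m6a_peaks_ctl", cc$n_ctl[cc$subgenome == "all"])
    add("m6a_peaks_wl", cc$n_wl[cc$subgenome == "all"])
    add("m6a_peak_loss_fraction", -cc$delta_frac[cc$subgenome == "all"])
    if (!is.null(res$m6a$sharing)) {
      for (i in 1:3) {
        add(paste0("m6a_sharing_", res$m6a$sharing$class[i]),
            res$m6a$sharing$fraction[i])
      }
    }
    dm <- res$m6a$differential
    if (nrow(dm) > 0) {
      dsub <- subg[dm$gene_id[dm$differential]]
      add("m6a_differential_A", sum(dsub == "A", na.rm = TRUE))
      add("m6a_differential_B", sum(dsub == "B", na.rm = TRUE))
    }
  }

  summary_df <- do.call(rbind, summ)
  write_tsv(summary_df, file.path(outdir, "summary.tsv"))
  res$summary <- summary_df
  invisible(res)
}
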