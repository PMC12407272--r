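test_that("TE content merges overlaps and is split-invariant", {
  genome <- genome_table(c("chr1A", "chr1B"), c("A", "B"), c(1e6, 1e6))
  tes <- data.frame(chrom = "chr1A", start = 0, end = 5e5)
  expect_equal(te_content(tes, genome)$fraction, c(0.5, 0))
  # overlapping and split intervals cover the same bases
  tes2 <- data.frame(chrom = "chr1A", start = c(0, 2e5, 25e4),
                     end = c(3e5, 5e5, 28e4))
  expect_equal(te_content(tes2, genome)$fraction[1], 0.5)
  tes3 <- data.frame(chrom = "chr1A", start = c(0, 1e5, 2e5, 3e5, 4e5),
                     end = c(1e5, 2e5, 3e5, 4e5, 5e5))
  expect_equal(te_content(tes3, genome), te_content(tes, genome))
})

test_that("simulated TE densities order the subgenome TE fractions", {
  b <- tiny_bundle()
  tc <- te_content(b$tes, b$genome)
  expect_gt(tc$fraction[tc$subgenome == "B"],
            tc$fraction[tc$subgenome == "A"])
})

test_that("nearest TE distance uses half-open gap arithmetic", {
  gs <- toy_gene_set(data.frame(gene_id = c("gA", "gB"),
                                chrom = c("chr1A", "chr1B"), strand = "+",
                                start = c(1000, 1000), end = c(2000, 2000)))
  tes <- data.frame(chrom = c("chr1A", "chr1B"), start = c(2000, 2500),
                    end = c(2300, 3000))
  r <- nearest_te_distance(gs, tes)
  expect_equal(r$distances$distance[r$distances$gene_id == "gA"], 0)
  expect_equal(r$distances$distance[r$distances$gene_id == "gB"], 500)
  # chromosome without TEs -> undefined, excluded, counted
  tes2 <- tes[1, ]
  r2 <- nearest_te_distance(gs, tes2)
  expect_true(is.na(r2$distances$distance[r2$distances$gene_id == "gB"]))
  expect_equal(r2$n_undefined, 1)
})

test_that("denser TEs in B bring genes closer there", {
  # sparse TEs so that gene-TE gaps are mostly positive
  cfg <- tiny_config(te_density_A = 40, te_density_B = 90,
                     te_len_mean = 800)
  sc <- subdom:::simulate_genome(cfg)
  te <- simulate_tes(sc, cfg)
  r <- nearest_te_distance(sc$genes, te$tes)
  expect_lt(r$medians$median_bp[r$medians$subgenome == "B"],
            r$medians$median_bp[r$medians$subgenome == "A"])
  expect_lt(r$test$p_value, 0.05)
})

test_that("solo:intact ratio and LTR age follow their definitions", {
  ltrs <- data.frame(id = sprintf("l%02d", 1:40),
                     subgenome = rep(c("A", "B"), c(37, 3)),
                     kind = c(rep("solo", 27), rep("intact", 10),
                              rep("intact", 3)),
                     ltr_divergence = NA, family = "Copia")
  r <- solo_intact_ratio(ltrs)
  expect_equal(r$ratio[r$subgenome == "A"], 2.7)
  expect_equal(r$ratio[r$subgenome == "B"], 0)
  expect_equal(solo_intact_ratio(ltrs[sample(nrow(ltrs)), ]), r)
  expect_error(solo_intact_ratio(ltrs[ltrs$kind == "solo", ]), "intact")

  expect_equal(ltr_insertion_age(0, 7e-9), 0)
  expect_equal(ltr_insertion_age(0.07, 7e-9), 5e6)
  expect_equal(ltr_insertion_age(c(0.01, 0.02), 1e-8),
               c(5e5, 1e6))  # linear in divergence
  expect_error(ltr_insertion_age(0.05, 0), "positive")
})

test_that("global methylation is read-weighted, not site-averaged", {
  genome <- genome_table("chr1A", "A", 1e4)
  meth <- data.frame(chrom = "chr1A", pos = c(10, 20), context = "CG",
                     mc_count = c(10, 0), total_count = c(10, 30))
  g <- global_methylation(meth, genome)
  expect_equal(g$level[g$context == "CG"], 0.25)
  meth2 <- data.frame(chrom = "chr1A", pos = 1:5 * 10, context = "CHH",
                      mc_count = 8, total_count = 10)
  g2 <- global_methylation(meth2, genome)
  expect_equal(g2$level[g2$context == "CHH"], 0.8)
  expect_true(is.na(g2$level[g2$context == "CG"]))  # no covered stratum
})

test_that("simulated plateau levels are recovered inside TEs", {
  cfg <- tiny_config(meth_site_spacing = 60)
  sc <- subdom:::simulate_genome(cfg)
  te <- simulate_tes(sc, cfg)
  meth <- simulate_methylome(te$tes, sc, cfg)
  mp <- metaprofile(meth, te$tes)
  for (ctx in c("CG", "CHG", "CHH")) {
    body <- mp$level[mp$context == ctx & mp$bin_kind == "body"]
    expect_lt(abs(mean(body) - cfg$meth_te_level[[ctx]]), 0.01)
  }
})

test_that("metaprofile reproduces step functions and respects strand", {
  pos <- seq(0, 9999, by = 25)
  inside <- pos >= 4000 & pos < 6000
  meth <- data.frame(chrom = "chr1A", pos = pos, context = "CG",
                     mc_count = ifelse(inside, 18, 2), total_count = 20)
  regions <- data.frame(chrom = "chr1A", start = 4000, end = 6000)
  mp <- metaprofile(meth, regions, flank_bp = 2000, body_bins = 10,
                    flank_bins = 10)
  cg <- mp[mp$context == "CG", ]
  expect_equal(cg$level[cg$bin_kind == "body"], rep(0.9, 10))
  expect_equal(cg$level[cg$bin_kind == "upstream"], rep(0.1, 10))
  expect_equal(cg$level[cg$bin_kind == "downstream"], rep(0.1, 10))

  # uniform methylation -> flat profile
  meth$mc_count <- 10
  mpu <- metaprofile(meth, regions, body_bins = 5, flank_bins = 5)
  expect_true(all(abs(mpu$level[!is.na(mpu$level)] - 0.5) < 1e-12))

  # minus-strand region mirrors the plus-strand profile of reflected data
  grad <- data.frame(chrom = "chr1A", pos = pos, context = "CG",
                     mc_count = round(19 * (pos / max(pos))) + 1,
                     total_count = 20)
  rplus <- data.frame(chrom = "chr1A", start = 4000, end = 6000,
                      strand = "+")
  rminus <- data.frame(chrom = "chr1A", start = 4000, end = 6000,
                       strand = "-")
  grad_rev <- grad
  grad_rev$mc_count <- rev(grad$mc_count)
  mp_p <- metaprofile(grad, rplus, body_bins = 10, flank_bins = 10)
  mp_m <- metaprofile(grad_rev, rminus, body_bins = 10, flank_bins = 10)
  expect_equal(mp_m$level, mp_p$level, tolerance = 1e-9)
})

test_that("flank methylation decays monotonically from TE edges", {
  cfg <- tiny_config(meth_site_spacing = 60)
  sc <- subdom:::simulate_genome(cfg)
  te <- simulate_tes(sc, cfg)
  meth <- simulate_methylome(te$tes, sc, cfg)
  mp <- metaprofile(meth, te$tes)
  for (ctx in c("CG", "CHG")) {
    fl <- mp[mp$context == ctx & mp$bin_kind == "downstream", ]
    ct <- suppressWarnings(stats::cor.test(fl$bin_index, fl$level,
                                           method = "spearman"))
    expect_lt(ct$estimate, 0)
    expect_lt(ct$p.value, 0.01)
  }
})
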