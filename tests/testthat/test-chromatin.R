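toy_two_genes <- function() {
  toy_gene_set(data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1A", strand = c("+", "-"),
    start = c(20000, 50000), end = c(22000, 52000)))
}

test_that("position classes follow the genic > proximal > distal priority", {
  gs <- toy_two_genes()   # g1 TSS at 20000 (+), g2 TSS at 51999 (-)
  acrs <- data.frame(
    chrom = "chr1A",
    start = c(21000, 15000, 13000, 12000, 52100),
    end = c(21300, 15300, 15000, 12300, 52400),
    acr_id = paste0("a", 1:5), stringsAsFactors = FALSE)
  cls <- classify_position(acrs, gs, proximal_bp = 5000)
  # a1 overlaps g1's body -> genic even though near a TSS
  expect_equal(cls$position_class[1], "genic")
  # a2 ends 4700 bp upstream of g1 -> proximal
  expect_equal(cls$position_class[2], "proximal")
  # a3 ends exactly 5000 bp upstream of the TSS -> proximal (inclusive)
  expect_equal(cls$position_class[3], "proximal")
  # a4 ends 7700 upstream -> distal
  expect_equal(cls$position_class[4], "distal")
  # a5 starts 101 bp past g2's TSS on the minus strand -> proximal to g2
  expect_equal(cls$position_class[5], "proximal")
  expect_equal(cls$nearest_gene[5], "g2")
  # classes partition the set
  expect_true(all(cls$position_class %in% c("genic", "proximal", "distal")))
})

test_that("proximal rates recover simulated ACR probabilities", {
  b <- tiny_bundle()
  cls <- classify_position(b$acrs, b$genes)
  r <- acr_per_gene(cls, b$genes)
  pa <- r$rates$rate[r$rates$subgenome == "A"]
  pb <- r$rates$rate[r$rates$subgenome == "B"]
  expect_lt(abs(pa - 0.8), 0.05)
  # B loses acr_indel_loss_prob of its ACRs on top of 1 - acr_prob_B
  expect_lt(abs(pb - 0.5 * 0.9), 0.05)
  expect_lt(r$test$p_value, 0.01)
  # counts invariant to input order
  cls2 <- cls[rev(seq_len(nrow(cls))), ]
  r2 <- acr_per_gene(cls2, b$genes)
  expect_equal(r2$per_gene, r$per_gene)
})

test_that("conservation classification matches simulator truth", {
  b <- tiny_bundle()
  map <- pair_homoeologs(b$genes, b$anchors)
  cls <- classify_position(b$acrs, b$genes)
  cons <- classify_conservation(cls, b$genes, map)
  one <- cons[!duplicated(cons$acr_id), ]
  truth <- b$truth$acrs
  m <- merge(one[, c("acr_id", "conservation_class", "no_anchor")],
             truth[, c("acr_id", "truth")], by = "acr_id")
  # score conserved-vs-specific as a binary classification
  called_cons <- m$conservation_class == "conserved"
  true_cons <- m$truth == "conserved"
  tp <- sum(called_cons & true_cons)
  prec <- tp / sum(called_cons); rec <- tp / sum(true_cons)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.95)
  # specific calls carry the right subgenome label
  spec <- m[m$truth %in% c("A-specific", "B-specific"), ]
  expect_gte(mean(spec$conservation_class == spec$truth), 0.9)
  # no-anchor flag marks singleton-anchored ACRs
  expect_gte(mean(m$no_anchor[m$truth == "specific-noanchor"]), 0.9)
  # symmetry: conserved partners are mutual
  co <- one[one$conservation_class == "conserved" & !is.na(one$partner_acr), ]
  back <- one$partner_acr[match(co$partner_acr, one$acr_id)]
  expect_gte(mean(back == co$acr_id, na.rm = TRUE), 0.95)
})

test_that("variant density normalises per kb and separates classes", {
  cons <- data.frame(chrom = "chr1A", start = 1000, end = 1600,
                     acr_id = "a1", conservation_class = "A-specific",
                     proj_chrom = NA, proj_start = NA, proj_end = NA,
                     stringsAsFactors = FALSE)
  variants <- data.frame(chrom = "chr1A", pos = c(1100, 1200, 1300, 5000),
                         ref = "A", alt = "T", type = "SNP",
                         subA = "alt", subB = "ref", progA = "alt",
                         progB = "ref", stringsAsFactors = FALSE)
  d <- acr_variant_density(cons, variants)
  expect_equal(d$per_acr$density_per_kb, 5)
  expect_equal(acr_variant_density(cons, variants[0, ])$per_acr$n_variants, 0)

  b <- tiny_bundle()
  map <- pair_homoeologs(b$genes, b$anchors)
  cc <- classify_conservation(classify_position(b$acrs, b$genes),
                              b$genes, map)
  dv <- acr_variant_density(cc[!duplicated(cc$acr_id), ], b$variants)
  agg <- tapply(dv$per_acr$density_per_kb,
                dv$per_acr$conservation_class == "conserved", mean)
  expect_gt(agg[["FALSE"]], agg[["TRUE"]])
  expect_lt(dv$test$p_value, 0.01)
})

test_that("ancestry attribution counts informative matches only", {
  acr <- data.frame(chrom = "chr1A", start = 1000, end = 1600,
                    acr_id = "a1", subgenome = "A",
                    conservation_class = "A-specific",
                    stringsAsFactors = FALSE)
  v <- data.frame(chrom = "chr1A", pos = c(1100, 1200, 1300),
                  ref = "A", alt = "T", type = "SNP",
                  subA = c("alt", "alt", "alt"), subB = "ref",
                  progA = c("alt", "ref", NA), progB = "ref",
                  stringsAsFactors = FALSE)
  r <- ancestry_attribution(v, acr)
  expect_equal(r$informative, 2)   # missing progenitor call excluded
  expect_equal(r$fraction, 0.5)
  v$progA <- "alt"
  expect_equal(ancestry_attribution(v, acr)$fraction, 1)
  v$progA <- NA
  expect_error(ancestry_attribution(v, acr), "informative")
})

test_that("tissue-specific ACRs split constitutive from private loci", {
  acrs <- data.frame(
    chrom = "chr1A",
    start = c(rep(1000, 3), rep(5000, 3), 9000, 12000),
    end = c(rep(1300, 3), rep(5300, 3), 9300, 12300),
    acr_id = c(rep("c1", 3), rep("c2", 3), "p1", "p2"),
    score = c(rep(5, 6), 9, 7),
    tissue = c("leaf", "root", "stem", "leaf", "root", "stem",
               "leaf", "root"),
    nearest_gene = c(rep("g1", 3), rep("g2", 3), "g3", "g4"),
    stringsAsFactors = FALSE)
  ts <- tissue_specific_acrs(acrs, top_n = 10)
  expect_equal(nrow(ts$constitutive), 2)
  expect_equal(nrow(ts$specific$leaf), 1)
  expect_equal(ts$specific$leaf$nearest_gene, "g3")
  expect_equal(nrow(ts$specific$stem), 0)
  # identical sets across tissues -> no specific loci
  acrs2 <- acrs[1:6, ]
  ts2 <- tissue_specific_acrs(acrs2, top_n = 10)
  expect_equal(sum(vapply(ts2$specific, nrow, 0L)), 0L)
  expect_error(tissue_specific_acrs(acrs[acrs$tissue == "leaf", ]),
               "2 tissues")
})

test_that("planted tissue-linked terms enrich in tissue-specific ACRs", {
  b <- tiny_bundle()
  cls <- classify_position(b$acrs, b$genes)
  ts <- tissue_specific_acrs(cls, term_map = b$term_map, top_n = 1000)
  enr <- ts$enrichment
  planted <- enr[paste0("TERM_", enr$tissue) == enr$term, ]
  expect_true(any(planted$adj_p < 0.05))
  expect_gt(mean(planted$fold), 1)
})
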