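test_that("TPM follows the closed form and normalises columns", {
  k <- matrix(c(100, 100), ncol = 1,
              dimnames = list(c("g1", "g2"), "s1"))
  tpm <- compute_tpm(k, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  single <- compute_tpm(matrix(5, 1, 1, dimnames = list("g", "s")),
                        c(g = 500))
  expect_equal(unname(single[1, 1]), 1e6)
  set.seed(2)
  k2 <- matrix(rpois(60, 40), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  tpm2 <- compute_tpm(k2, setNames(sample(500:3000, 10), paste0("g", 1:10)))
  expect_equal(unname(colSums(tpm2)), rep(1e6, 6), tolerance = 1e-6)
  k2[, 3] <- 0
  expect_error(compute_tpm(k2, setNames(rep(1000, 10), paste0("g", 1:10))),
               "s3")
})

test_that("expressed-gene filter uses a strict threshold", {
  tpm <- rbind(g1 = c(0.1, 0.1), g2 = c(0.2, 0), g3 = c(0, 0))
  colnames(tpm) <- c("s1", "s2")
  expect_equal(filter_expressed(tpm, 0.1)$genes, "g2")
  expect_equal(sort(filter_expressed(tpm, 0)$genes), c("g1", "g2"))
  f <- filter_expressed(tpm, 0.1, subgenome = c(g1 = "A", g2 = "A", g3 = "B"))
  expect_equal(f$summary$expressed[f$summary$subgenome == "A"], 1L)
})

test_that("size factors recover depth scaling exactly", {
  set.seed(11)
  base <- rpois(500, 50) + 1
  k <- cbind(s1 = base, s2 = rpois(500, base), s3 = base * 2L)
  rownames(k) <- paste0("g", 1:500)
  sf <- size_factors(k)
  expect_equal(sf["s3"] / sf["s1"], c(s3 = 2), tolerance = 1e-6)
})

test_that("NB Wald test is antisymmetric and excludes empty genes", {
  set.seed(12)
  k <- matrix(rnbinom(600 * 6, mu = 80, size = 20), 600, 6,
              dimnames = list(paste0("g", 1:600), paste0("s", 1:6)))
  k[5, ] <- 0
  a <- paste0("s", 1:3); b <- paste0("s", 4:6)
  r1 <- nb_differential(k, a, b)
  r2 <- nb_differential(k, b, a)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
  expect_equal(attr(r1, "excluded"), "g5")
  expect_false("g5" %in% r1$gene_id)
})

test_that("homoeolog bias classifies truthfully and symmetrically", {
  b <- tiny_bundle()
  map <- pair_homoeologs(b$genes, b$anchors)
  bias <- homoeolog_bias(b$counts, b$samples, map)
  tp <- b$truth$pairs[b$truth$pairs$class == "pair", ]
  m <- merge(bias$calls, tp[, c("gene_a", "bias_class")], by = "gene_a")
  truth_frac <- mean(m$bias_class != "unbiased")
  called_frac <- mean(m$class != "unbiased")
  expect_lt(abs(called_frac - truth_frac), 0.05)
  both <- m$class != "unbiased" & m$bias_class != "unbiased"
  acc <- mean((m$class[both] == "A-dominant") == (m$bias_class[both] == "A"))
  expect_gte(acc, 0.95)

  # swapping subgenome labels flips every class
  b2 <- b
  swap <- function(x) chartr("AB", "BA", x)
  b2$genes$genes$subgenome <- swap(b$genes$genes$subgenome)
  map_sw <- map
  map_sw$pairs <- data.frame(gene_a = map$pairs$gene_b,
                             gene_b = map$pairs$gene_a,
                             similarity = map$pairs$similarity,
                             block_id = map$pairs$block_id)
  bias_sw <- homoeolog_bias(b$counts, b$samples, map_sw)
  key <- paste(bias$calls$gene_a, bias$calls$gene_b)
  key_sw <- paste(bias_sw$calls$gene_b, bias_sw$calls$gene_a)
  cl <- bias$calls$class[match(key_sw, key)]
  flip <- c("A-dominant" = "B-dominant", "B-dominant" = "A-dominant",
            unbiased = "unbiased")
  expect_equal(unname(flip[cl]), bias_sw$calls$class)
})

test_that("bias calls are invariant to scaling one library", {
  b <- tiny_bundle()
  map <- pair_homoeologs(b$genes, b$anchors)
  k <- b$counts
  k[, "leaf_2"] <- k[, "leaf_2"] * 3L
  bias0 <- homoeolog_bias(b$counts, b$samples, map)
  bias1 <- homoeolog_bias(k, b$samples, map)
  agree <- mean(bias0$calls$class ==
                  bias1$calls$class[match(bias0$calls$pair,
                                          bias1$calls$pair)])
  expect_gte(agree, 0.98)
})

test_that("identical homoeolog counts give no bias calls", {
  set.seed(14)
  n <- 80
  base <- matrix(rnbinom(n * 15, mu = 100, size = 20), n, 15)
  k <- rbind(base, base)
  rownames(k) <- c(sprintf("Av_01Ag%04d", 1:n), sprintf("Av_01Bg%04d", 1:n))
  tissues <- rep(c("leaf", "root", "stem", "peel", "pulp"), each = 3)
  colnames(k) <- paste0(tissues, "_", rep(1:3, 5))
  samples <- data.frame(sample = colnames(k), tissue = tissues,
                        condition = "", replicate = rep(1:3, 5))
  map <- list(pairs = data.frame(gene_a = rownames(k)[1:n],
                                 gene_b = rownames(k)[n + 1:n],
                                 similarity = 1, block_id = 1))
  class(map) <- "homoeolog_map"
  bias <- homoeolog_bias(k, samples, map)
  expect_true(all(bias$calls$class == "unbiased"))
})

test_that("singleton comparison detects a planted shift and stays null", {
  set.seed(15)
  n <- 300
  tpm <- matrix(rlnorm(2 * n * 4, log(20), 1), 2 * n, 4)
  rownames(tpm) <- paste0("g", 1:(2 * n))
  map <- list(singletons_a = paste0("g", 1:n),
              singletons_b = paste0("g", n + 1:n))
  class(map) <- "homoeolog_map"
  r0 <- singleton_comparison(tpm, map)
  expect_gt(r0$p_value, 0.001)      # same distribution
  tpm2 <- tpm
  tpm2[1:n, ] <- tpm2[1:n, ] * 2
  r1 <- singleton_comparison(tpm2, map)
  expect_lt(r1$p_value, 0.01)
  expect_gt(r1$effect, 0)
  # single-sample table works directly
  r2 <- singleton_comparison(tpm2[, 1, drop = FALSE], map)
  expect_lt(r2$p_value, 0.05)
  map$singletons_a <- character(0)
  expect_error(singleton_comparison(tpm, map), "non-empty")
})

test_that("per-subgenome DEG summary partitions counts", {
  de <- data.frame(gene_id = paste0("g", 1:6),
                   log2fc = c(2, -2, 1.5, 0, -3, 2),
                   deg = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  sub <- setNames(rep(c("A", "B"), each = 3), paste0("g", 1:6))
  s <- subgenome_deg_summary(de, sub)
  expect_equal(s$up + s$down, s$total)
  expect_equal(s$total[s$subgenome == "A"], 3L)
  expect_equal(s$down[s$subgenome == "B"], 1L)
  expect_equal(s$rate, s$total / 3)
  de$deg <- FALSE
  expect_equal(sum(subgenome_deg_summary(de, sub)$total), 0L)
})

test_that("NB test agrees with an independent DESeq2 fit on a fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  n <- 300
  mu <- rlnorm(n, log(120), 0.8)
  lfc <- c(rep(0, 250), runif(50, 1.5, 2.5) * sign(rnorm(50)))
  k <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 10), n, 3),
             matrix(rnbinom(n * 3, mu = mu * 2^lfc, size = 10), n, 3))
  dimnames(k) <- list(paste0("g", 1:n), paste0("s", 1:6))
  ours <- nb_differential(k, paste0("s", 1:3), paste0("s", 4:6))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    k, data.frame(cond = factor(rep(c("a", "b"), each = 3))), ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  common <- intersect(ours$gene_id, rownames(res))
  lfc_cor <- cor(ours$log2fc[match(common, ours$gene_id)],
                 res$log2FoldChange[match(common, rownames(res))])
  expect_gt(lfc_cor, 0.97)
  sig_ours <- ours$gene_id[ours$adj_p < 0.05]
  sig_ref <- rownames(res)[!is.na(res$padj) & res$padj < 0.05]
  jac <- length(intersect(sig_ours, sig_ref)) /
    length(union(sig_ours, sig_ref))
  expect_gt(jac, 0.8)
})
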