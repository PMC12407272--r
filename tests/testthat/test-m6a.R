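flat_windows <- function(n_genes = 20, nwin = 40, ip = 10, input = 10,
                         condition = "CTL") {
  d <- expand.grid(win_index = seq_len(nwin),
                   gene_id = sprintf("g%03d", seq_len(n_genes)),
                   stringsAsFactors = FALSE)[, c("gene_id", "win_index")]
  d$start <- (d$win_index - 1) * 50
  d$end <- d$win_index * 50
  d$ip <- ip; d$input <- input; d$condition <- condition
  d
}

test_that("equal IP and input with equal libraries yields no peaks", {
  set.seed(50)
  w <- flat_windows()
  w$ip <- rpois(nrow(w), 10); w$input <- rpois(nrow(w), 10)
  pk <- call_peaks(w, ip_lib = 1e6, input_lib = 1e6)
  expect_lt(nrow(pk) / nrow(w), 0.03)   # type-I only at shallow depth
})

test_that("a strongly enriched window is called with the exact Fisher p", {
  w <- flat_windows(n_genes = 1, nwin = 5)
  w$ip <- c(10, 40, 10, 10, 10); w$input <- 10
  pk <- call_peaks(w, ip_lib = 1e6, input_lib = 1e6)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$tx_start, pk$tx_end), c(50, 100))
  ref <- stats::fisher.test(matrix(c(40, 10, 1e6 - 40, 1e6 - 10), 2))
  expect_equal(pk$p, ref$p.value, tolerance = 1e-7)
})

test_that("the ratio threshold is inclusive and p strict", {
  # input_lib twice ip_lib makes the normalised ratio exactly 2 at ip == input
  w <- flat_windows(n_genes = 1, nwin = 3)
  w$ip <- c(1, 30, 1); w$input <- c(1, 30, 1)
  pk <- call_peaks(w, ip_lib = 1e6, input_lib = 2e6)
  expect_equal(nrow(pk), 1)   # ratio == 2 (inclusive) and p < 0.05
  # same counts but higher p: a tiny window is not significant
  w2 <- flat_windows(n_genes = 1, nwin = 1)
  w2$ip <- 2; w2$input <- 2
  expect_equal(nrow(call_peaks(w2, ip_lib = 1e6, input_lib = 2e6)), 0)
})

test_that("adjacent significant windows merge and conserve evidence", {
  w <- flat_windows(n_genes = 2, nwin = 10)
  w$ip[w$gene_id == "g001" & w$win_index %in% 3:5] <- 50
  w$ip[w$gene_id == "g002" & w$win_index %in% c(2, 7)] <- 50
  pk <- call_peaks(w, ip_lib = 1e6, input_lib = 1e6)
  p1 <- pk[pk$gene_id == "g001", ]
  expect_equal(nrow(p1), 1)
  expect_equal(p1$n_windows, 3L)
  expect_equal(c(p1$tx_start, p1$tx_end), c(100, 250))
  expect_equal(nrow(pk[pk$gene_id == "g002", ]), 2)  # non-adjacent stay split
  # peak p is the minimum of its windows; log2 ratio is count-weighted
  expect_lte(p1$p, min(pk$p[pk$gene_id == "g002"]))
})

test_that("feature annotation uses max overlap with 3'UTR priority", {
  gs <- tiny_bundle()$genes
  gid <- gs$genes$gene_id[1]
  peaks <- data.frame(gene_id = c(gid, gid, gid, "missing"),
                      tx_start = c(1800, 1650, 100, 0),
                      tx_end = c(1900, 1750, 200, 100),
                      log2_ratio = 2, p = 0.001, adj_p = 0.01,
                      stringsAsFactors = FALSE)
  expect_warning(ann <- annotate_feature(peaks, gs), "unassigned")
  expect_equal(ann$peaks$feature,
               c("3'UTR", "3'UTR", "5'UTR", "unassigned"))
  # (1650,1750) straddles CDS/3'UTR with equal 50/50 overlap -> 3'UTR
  expect_equal(ann$enrichment$feature, c("5'UTR", "CDS", "3'UTR"))
})

test_that("simulated 3'UTR weight is recovered by annotation", {
  b <- tiny_bundle()
  w <- b$m6a_windows
  pk <- call_peaks(w[w$condition == "CTL", ])
  ann <- annotate_feature(pk, b$genes)
  tr <- b$truth$m6a
  frac3 <- mean(ann$peaks$feature == "3'UTR")
  expect_lt(abs(frac3 - mean(tr$feature == "3'UTR")), 0.05)
  # every called peak overlapping a true peak gets the true feature
  m <- merge(ann$peaks, tr, by = "gene_id")
  mm <- m[m$tx_start.x < m$tx_end.y & m$tx_end.x > m$tx_start.y, ]
  expect_equal(mean(mm$feature.x == mm$feature.y), 1)
  expect_gt(ann$enrichment$enrichment[ann$enrichment$feature == "3'UTR"], 2)
})

test_that("peak-gene summaries conserve totals", {
  peaks <- data.frame(gene_id = c("g1", "g1", "g2"), tx_start = 0,
                      tx_end = 50)
  s <- peak_gene_summary(peaks)
  expect_equal(s$n_genes, 2L)
  expect_equal(sum(as.integer(names(s$histogram)) * s$histogram), 3)
  empty <- peak_gene_summary(peaks[0, ])
  expect_equal(empty$n_genes, 0L)
})

test_that("homoeolog sharing fractions are computed over pair members", {
  map <- list(pairs = data.frame(gene_a = c("a1", "a2", "a3"),
                                 gene_b = c("b1", "b2", "b3")))
  class(map) <- "homoeolog_map"
  peaks <- data.frame(gene_id = c("a1", "b1", "a2"))
  s <- homoeolog_sharing(peaks, map)
  expect_equal(s$n_genes, c(2L, 1L, 0L))
  expect_equal(sum(s$fraction), 1)
  all_m <- homoeolog_sharing(data.frame(gene_id = c("a1", "b1", "a2", "b2",
                                                    "a3", "b3")), map)
  expect_equal(all_m$fraction[all_m$class == "shared"], 1)
})

test_that("simulated sharing structure is recovered within 3 points", {
  b <- tiny_bundle()
  w <- b$m6a_windows
  map <- pair_homoeologs(b$genes, b$anchors)
  pk <- call_peaks(w[w$condition == "CTL", ])
  s <- homoeolog_sharing(pk, map)
  expect_lt(abs(s$fraction[s$class == "shared"] - 0.82), 0.04)
  expect_lt(abs(s$fraction[s$class == "A-specific"] - 0.15), 0.04)
  expect_lt(abs(s$fraction[s$class == "B-specific"] - 0.03), 0.03)
})

test_that("condition comparison is null on identical inputs and errors empty", {
  b <- tiny_bundle()
  sub <- setNames(b$genes$genes$subgenome, b$genes$genes$gene_id)
  w <- b$m6a_windows
  pk <- call_peaks(w[w$condition == "CTL", ])
  ann <- annotate_feature(pk, b$genes)$peaks
  cmp <- condition_compare(ann, ann, sub)
  expect_equal(cmp$counts$delta_frac, rep(0, 3))
  expect_gt(cmp$tests$between_conditions$p_value, 0.9)
  expect_error(condition_compare(ann[0, ], ann, sub), "control")
})

test_that("differential m6A flags planted drops and is antisymmetric", {
  b <- tiny_bundle()
  w <- b$m6a_windows
  pk <- call_peaks_by_condition(w)
  dm <- differential_m6a(w, pk$CTL, pk$WL)
  truth <- b$truth$m6a
  part <- truth$gene_id[truth$partial_drop & !truth$lost_in_wl]
  null_g <- truth$gene_id[!truth$partial_drop & !truth$lost_in_wl]
  sens <- sum(dm$differential & dm$gene_id %in% part) / length(part)
  fpr <- sum(dm$differential & dm$gene_id %in% null_g) /
    sum(dm$gene_id %in% null_g)
  expect_gte(sens, 0.35)
  expect_lte(fpr, 0.02)
  expect_true(all(dm$dlog2_ratio[dm$differential &
                                   dm$gene_id %in% part] < 0))
  # swapping conditions negates the effect
  w_sw <- w
  w_sw$condition <- ifelse(w$condition == "CTL", "WL", "CTL")
  dm_sw <- differential_m6a(w_sw, pk$WL, pk$CTL)
  m <- merge(dm, dm_sw, by = c("gene_id", "tx_start"))
  expect_gt(cor(m$dlog2_ratio.x, -m$dlog2_ratio.y), 0.99)
})

test_that("expression integration cross-tabulates and detects coupling", {
  set.seed(55)
  # planted repression coupling: m6A down genes mostly expression-up
  n <- 120
  m6a_dir <- rep(c(-1, 1), each = n / 2)
  expr_dir <- ifelse(m6a_dir < 0,
                     ifelse(runif(n) < 0.8, 1, -1),
                     ifelse(runif(n) < 0.5, 1, -1))
  dm <- data.frame(gene_id = paste0("g", 1:n), tx_start = 0, tx_end = 100,
                   dlog2_ratio = m6a_dir * runif(n, 1, 2),
                   p = 0.001, adj_p = 0.01, differential = TRUE)
  de <- data.frame(gene_id = paste0("g", 1:n),
                   log2fc = expr_dir * runif(n, 1.2, 3),
                   deg = TRUE)
  r <- integrate_de_m6a(dm, de)
  expect_equal(sum(r$table), n)
  expect_lt(r$test$effect, 1)
  expect_lt(r$test$p_value, 0.05)
  # independent directions: odds ratio near 1
  de2 <- de
  de2$log2fc <- sample(c(-1, 1), n, TRUE) * runif(n, 1.2, 3)
  r2 <- integrate_de_m6a(dm, de2)
  expect_gt(r2$test$p_value, 0.001)
  # empty intersection warns
  de3 <- de[0, ]
  expect_warning(r3 <- integrate_de_m6a(dm, de3), "no gene")
  expect_equal(sum(r3$table), 0)
})

test_that("peak calling is invariant to uniform library scaling", {
  b <- tiny_bundle()
  w <- b$m6a_windows[b$m6a_windows$condition == "CTL", ]
  pk1 <- call_peaks(w)
  pk2 <- call_peaks(w, ip_lib = sum(w$ip) * 10, input_lib = sum(w$input) * 10)
  expect_equal(pk1[, c("gene_id", "tx_start", "tx_end")],
               pk2[, c("gene_id", "tx_start", "tx_end")])
})
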