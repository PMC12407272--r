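#' Read / write 6-column BED
#'
#' Intervals are 0-based half-open in both the file and the in-memory
#' table, so the two functions round-trip exactly. Scores are clipped to
#' [0, 1000] on write, per the BED specification.
#'
#' @param path File path.
#' @return data.frame chrom, start, end, name, score, strand.
#' @rdname bed_io
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"),
                         colClasses = c("character", "numeric", "numeric",
                                        "character", "numeric", "character"))
  if (any(d$start >= d$end)) stop("BED interval with start >= end")
  d
}

#' @param intervals data.frame with chrom, start, end, name, score, strand.
#' @rdname bed_io
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) { file.create(path); return(invisible(path)) }
  sc <- pmin(pmax(intervals$score, 0), 1000)
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                   intervals$chrom,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   intervals$name,
                   format(sc, scientific = FALSE, trim = TRUE),
                   intervals$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read per-cytosine methylation calls
#'
#' TSV with columns chrom, pos, context (CG/CHG/CHH), mc_count,
#' total_count. Sites with zero coverage are retained but their level is
#' undefined (NA) and they are excluded from weighted means.
#'
#' @param path File path.
#' @return data.frame chrom, pos, context, mc_count, total_count, level.
#' @export
read_methylation <- function(path) {
  d <- as.data.frame(data.table::fread(
    path, sep = "\t", header = TRUE,
    colClasses = list(character = 1, numeric = 2, character = 3,
                      numeric = 4:5)))
  names(d) <- c("chrom", "pos", "context", "mc_count", "total_count")
  bad <- setdiff(unique(d$context), c("CG", "CHG", "CHH"))
  if (length(bad) > 0) stop("unknown methylation context: ", bad[1])
  if (any(d$mc_count < 0) || any(d$total_count < d$mc_count)) {
    stop("methylation counts must satisfy 0 <= mc_count <= total_count")
  }
  d$level <- ifelse(d$total_count > 0, d$mc_count / d$total_count, NA_real_)
  d
}

#' @rdname read_methylation
#' @param meth Methylation table as returned by \code{read_methylation}.
#' @export
write_methylation <- function(meth, path) {
  data.table::fwrite(meth[, c("chrom", "pos", "context", "mc_count",
                              "total_count")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

VARIANT_SAMPLES <- c("subA", "subB", "progA", "progB")

#' Read variants with subgenome and progenitor genotypes
#'
#' Minimal VCF 4.x reader for the four named sample columns subA, subB,
#' progA and progB (the two subgenomes and the two progenitor species).
#' Multi-allelic sites are split into one record per alternate allele; a
#' genotype carrying a different alternate becomes missing for that
#' record. Genotypes are decoded to "ref"/"alt"/NA (homozygous calls
#' expected; heterozygous calls are treated as missing).
#'
#' @param path VCF file.
#' @return data.frame chrom, pos (1-based), ref, alt, type (SNP/InDel) and
#'   one column per sample.
#' @export
read_variants <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#CHROM")]
  if (length(hdr) != 1) stop("missing #CHROM header line in VCF")
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  missing_s <- setdiff(VARIANT_SAMPLES, cols)
  if (length(missing_s) > 0) {
    stop("VCF lacks required sample column: ", missing_s[1])
  }
  body <- ln[!startsWith(ln, "#")]
  if (length(body) == 0) {
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      type = character(0), stringsAsFactors = FALSE)
    for (s in VARIANT_SAMPLES) out[[s]] <- character(0)
    return(out)
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  si <- match(VARIANT_SAMPLES, cols)
  gt_tok <- function(x) sub(":.*", "", x)
  recs <- list()
  for (i in seq_len(nrow(f))) {
    alts <- strsplit(f[i, 5], ",", fixed = TRUE)[[1]]
    gts <- gt_tok(f[i, si])
    for (ai in seq_along(alts)) {
      dec <- vapply(gts, function(g) {
        a <- strsplit(g, "[/|]")[[1]]
        if (any(a == ".")) return(NA_character_)
        a <- as.integer(a)
        if (length(unique(a)) != 1) return(NA_character_)
        if (a[1] == 0) "ref" else if (a[1] == ai) "alt" else NA_character_
      }, character(1), USE.NAMES = FALSE)
      recs[[length(recs) + 1]] <- c(f[i, 1], f[i, 2], f[i, 4], alts[ai], dec)
    }
  }
  m <- do.call(rbind, recs)
  out <- data.frame(chrom = m[, 1], pos = as.numeric(m[, 2]), ref = m[, 3],
                    alt = m[, 4], stringsAsFactors = FALSE)
  out$type <- ifelse(nchar(out$ref) == 1 & nchar(out$alt) == 1,
                     "SNP", "InDel")
  for (k in seq_along(VARIANT_SAMPLES)) {
    out[[VARIANT_SAMPLES[k]]] <- m[, 4 + k]
  }
  out
}

#' Write a four-sample VCF
#'
#' @param variants data.frame as returned by \code{\link{read_variants}}.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", VARIANT_SAMPLES), collapse = "\t"))
  enc <- function(g) ifelse(is.na(g), "./.",
                            ifelse(g == "ref", "0/0", "1/1"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s\t%s\t%s\t%s",
                  variants$chrom, as.integer(variants$pos), variants$ref,
                  variants$alt, enc(variants$subA), enc(variants$subB),
                  enc(variants$progA), enc(variants$progB))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gene-by-sample count table
#'
#' TSV with a gene_id column followed by one integer column per sample.
#'
#' @param path File path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(d)
}

#' @rdname read_counts
#' @param counts Count matrix (gene rownames).
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}
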