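#' Genome description table
#'
#' @param chrom Character vector of chromosome ids (unique).
#' @param subgenome Subgenome label per chromosome, "A" or "B" (or
#'   "unplaced" for unanchored sequence).
#' @param length Chromosome lengths in bp (> 0).
#' @return A data.frame of class \code{subdom_genome}.
#' @export
genome_table <- function(chrom, subgenome, length) {
  if (anyDuplicated(chrom)) stop("chromosome ids must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (!all(subgenome %in% c("A", "B", "unplaced"))) {
    stop("subgenome labels must be 'A', 'B' or 'unplaced'")
  }
  g <- data.frame(chrom = as.character(chrom),
                  subgenome = as.character(subgenome),
                  length = as.numeric(length),
                  stringsAsFactors = FALSE)
  class(g) <- c("subdom_genome", "data.frame")
  g
}

#' Infer subgenome labels from chromosome names
#'
#' Accepts the "<n>A"/"<n>B" trailing-letter convention; an explicit
#' mapping (named vector chrom -> label) overrides it.
#'
#' @param chrom Chromosome ids.
#' @param mapping Optional named character vector of labels.
#' @return Character vector of labels ("A", "B", or "unplaced").
#' @export
subgenome_of <- function(chrom, mapping = NULL) {
  if (!is.null(mapping)) {
    lab <- unname(mapping[chrom])
    lab[is.na(lab)] <- "unplaced"
    return(lab)
  }
  last <- substring(chrom, nchar(chrom))
  ifelse(last %in% c("A", "B"), last, "unplaced")
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS (and UTR) features, converts the 1-based
#' closed GFF coordinates to the package's 0-based half-open convention,
#' keeps one representative mRNA per gene (longest summed CDS) and derives
#' UTRs from exons minus CDS when absent.
#'
#' @param path GFF3 file.
#' @param genome Optional \code{subdom_genome} used to label subgenomes;
#'   otherwise the chromosome-name convention is used.
#' @return A \code{gene_set}: list with \code{genes} (one row per gene:
#'   gene_id, chrom, strand, start, end, tss, subgenome) and
#'   \code{features} (gene_id, type in exon/CDS/five_prime_UTR/
#'   three_prime_UTR, start, end), all 0-based half-open.
#' @export
read_gff3 <- function(path, genome = NULL) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0) stop("empty GFF3 file: ", path)
  f <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) stop("malformed GFF3: expected 9 columns")
  f <- do.call(rbind, f)
  type <- f[, 3]
  keep <- type %in% c("gene", "mRNA", "transcript", "exon", "CDS",
                      "five_prime_UTR", "three_prime_UTR")
  f <- f[keep, , drop = FALSE]
  type <- f[, 3]
  type[type == "transcript"] <- "mRNA"
  attr_field <- f[, 9]
  ids <- vapply(attr_field, function(s) {
    m <- regmatches(s, regexpr("(^|;)ID=[^;]*", s))
    if (length(m) == 0) NA_character_ else sub(".*ID=", "", m)
  }, character(1), USE.NAMES = FALSE)
  parents <- vapply(attr_field, function(s) {
    m <- regmatches(s, regexpr("(^|;)Parent=[^;]*", s))
    if (length(m) == 0) NA_character_ else sub(".*Parent=", "", m)
  }, character(1), USE.NAMES = FALSE)
  df <- data.frame(chrom = f[, 1], type = type,
                   start = as.numeric(f[, 4]) - 1,  # to 0-based half-open
                   end = as.numeric(f[, 5]),
                   strand = f[, 7], id = ids, parent = parents,
                   stringsAsFactors = FALSE)

  gene_rows <- df[df$type == "gene", ]
  if (anyDuplicated(gene_rows$id)) stop("duplicate gene ids in GFF3")
  mrna_rows <- df[df$type == "mRNA", ]
  bad <- !(mrna_rows$parent %in% gene_rows$id)
  if (any(bad)) {
    stop("mRNA with unknown gene parent: ", mrna_rows$id[which(bad)[1]])
  }
  sub_rows <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                                "three_prime_UTR"), ]
  bad <- !(sub_rows$parent %in% mrna_rows$id)
  if (any(bad)) {
    b <- sub_rows[which(bad)[1], ]
    stop("feature with unknown mRNA parent: ",
         ifelse(is.na(b$id), b$parent, b$id))
  }

  # representative mRNA per gene: longest summed CDS, then longest span
  cds_len <- tapply(sub_rows$end[sub_rows$type == "CDS"] -
                      sub_rows$start[sub_rows$type == "CDS"],
                    sub_rows$parent[sub_rows$type == "CDS"], sum)
  mrna_rows$cds_len <- ifelse(mrna_rows$id %in% names(cds_len),
                              cds_len[mrna_rows$id], 0)
  mrna_rows$span <- mrna_rows$end - mrna_rows$start
  o <- order(mrna_rows$parent, -mrna_rows$cds_len, -mrna_rows$span)
  rep_mrna <- mrna_rows[o, ][!duplicated(mrna_rows$parent[o]), ]

  feats <- sub_rows[sub_rows$parent %in% rep_mrna$id, ]
  feats$gene_id <- rep_mrna$parent[match(feats$parent, rep_mrna$id)]

  out_feats <- vector("list", nrow(gene_rows))
  no_cds <- character(0)
  for (i in seq_len(nrow(gene_rows))) {
    gid <- gene_rows$id[i]
    fg <- feats[feats$gene_id == gid, ]
    ex <- fg[fg$type == "exon", c("start", "end")]
    cd <- fg[fg$type == "CDS", c("start", "end")]
    if (nrow(ex) == 0 && nrow(cd) > 0) ex <- cd  # tolerate exon-less mRNA
    if (nrow(cd) > 0 && nrow(ex) > 0) {
      if (!all(mapply(function(s, e) any(ex$start <= s & ex$end >= e),
                      cd$start, cd$end))) {
        stop("CDS outside exons for gene ", gid)
      }
    }
    u5 <- fg[fg$type == "five_prime_UTR", c("start", "end")]
    u3 <- fg[fg$type == "three_prime_UTR", c("start", "end")]
    if (nrow(cd) == 0) {
      no_cds <- c(no_cds, gid)
      u5 <- u3 <- ex[0, ]
    } else if (nrow(u5) == 0 && nrow(u3) == 0 && nrow(ex) > 0) {
      utr <- subtract_intervals(ex, cd)
      cmin <- min(cd$start); cmax <- max(cd$end)
      left <- utr[utr$end <= cmin, , drop = FALSE]
      right <- utr[utr$start >= cmax, , drop = FALSE]
      if (gene_rows$strand[i] == "+") { u5 <- left; u3 <- right }
      else { u5 <- right; u3 <- left }
    }
    blk <- function(d, ty) {
      if (nrow(d) == 0) return(NULL)
      data.frame(gene_id = gid, type = ty, start = d$start, end = d$end,
                 stringsAsFactors = FALSE)
    }
    out_feats[[i]] <- rbind(blk(ex, "exon"), blk(cd, "CDS"),
                            blk(u5, "five_prime_UTR"),
                            blk(u3, "three_prime_UTR"))
  }
  if (length(no_cds) > 0) {
    warning(length(no_cds), " gene(s) lack a CDS; UTRs left empty (e.g. ",
            no_cds[1], ")")
  }
  features <- do.call(rbind, out_feats)
  rownames(features) <- NULL
  genes <- data.frame(
    gene_id = gene_rows$id, chrom = gene_rows$chrom,
    strand = gene_rows$strand, start = gene_rows$start, end = gene_rows$end,
    tss = ifelse(gene_rows$strand == "+", gene_rows$start, gene_rows$end - 1),
    stringsAsFactors = FALSE)
  genes$subgenome <- if (is.null(genome)) subgenome_of(genes$chrom) else {
    subgenome_of(genes$chrom,
                 stats::setNames(genome$subgenome, genome$chrom))
  }
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  structure(list(genes = genes, features = features), class = "gene_set")
}

# set-difference of interval tables (0-based half-open data.frames)
subtract_intervals <- function(a, b) {
  if (nrow(b) == 0) return(a)
  ra <- IRanges::IRanges(a$start + 1, a$end)
  rb <- IRanges::IRanges(b$start + 1, b$end)
  d <- IRanges::setdiff(ra, rb)
  data.frame(start = IRanges::start(d) - 1, end = IRanges::end(d))
}

#' Write gene models as GFF3
#'
#' Inverse of \code{\link{read_gff3}}; converts back to 1-based closed
#' coordinates.
#'
#' @param gs A \code{gene_set}.
#' @param path Output path.
#' @export
write_gff3 <- function(gs, path) {
  g <- gs$genes
  ft <- gs$features
  lines <- c("##gff-version 3")
  gl <- sprintf("%s\tsubdom\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$chrom, g$start + 1, g$end, g$strand, g$gene_id)
  ml <- sprintf("%s\tsubdom\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                g$chrom, g$start + 1, g$end, g$strand, g$gene_id, g$gene_id)
  fchrom <- g$chrom[match(ft$gene_id, g$gene_id)]
  fstrand <- g$strand[match(ft$gene_id, g$gene_id)]
  fl <- sprintf("%s\tsubdom\t%s\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
                fchrom, ft$type, ft$start + 1, ft$end, fstrand, ft$gene_id)
  # interleave by gene to keep records grouped
  ord <- order(match(ft$gene_id, g$gene_id), ft$start,
               match(ft$type, c("exon", "five_prime_UTR", "CDS",
                                "three_prime_UTR")))
  body <- character(0)
  idx <- split(seq_along(fl)[ord], ft$gene_id[ord])
  for (i in seq_len(nrow(g))) {
    body <- c(body, gl[i], ml[i], fl[idx[[g$gene_id[i]]]])
  }
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Transcript-coordinate feature layout
#'
#' Lengths of the 5'UTR, CDS and 3'UTR of each gene's representative
#' transcript, defining its layout in 5'->3' transcript coordinates.
#'
#' @param gs A \code{gene_set}.
#' @return data.frame gene_id, len5, len_cds, len3, tx_len.
#' @export
transcript_layout <- function(gs) {
  ft <- gs$features
  lens <- function(ty) {
    sel <- ft$type == ty
    v <- tapply(ft$end[sel] - ft$start[sel], ft$gene_id[sel], sum)
    out <- stats::setNames(rep(0, nrow(gs$genes)), gs$genes$gene_id)
    out[names(v)] <- v
    out
  }
  l5 <- lens("five_prime_UTR"); lc <- lens("CDS"); l3 <- lens("three_prime_UTR")
  lex <- lens("exon")
  tx <- ifelse(lex > 0, lex, l5 + lc + l3)
  data.frame(gene_id = gs$genes$gene_id, len5 = as.numeric(l5),
             len_cds = as.numeric(lc), len3 = as.numeric(l3),
             tx_len = as.numeric(tx), stringsAsFactors = FALSE)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosomes\n")
  tab <- table(x$genes$subgenome)
  cat("  subgenomes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
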