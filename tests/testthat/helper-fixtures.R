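# Shared small fixtures, built once per test run.

tiny_config <- function(seed = 7, ...) {
  sim_config(n_chrom_per_subgenome = 2, genes_per_chrom = 150,
             seed = seed, ...)
}

.fixtures <- new.env(parent = emptyenv())

tiny_scaffold <- function() {
  if (is.null(.fixtures$scaffold)) {
    .fixtures$scaffold <- subdom:::simulate_genome(tiny_config())
  }
  .fixtures$scaffold
}

tiny_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    .fixtures$bundle <- generate_dataset(tiny_config())
  }
  .fixtures$bundle
}

# a hand-built gene set: two chromosomes (one per subgenome), simple
# single-exon genes with 200/600/200 bp UTR5/CDS/UTR3
toy_gene_set <- function(tab) {
  genes <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                      strand = tab$strand, start = tab$start,
                      end = tab$end,
                      tss = ifelse(tab$strand == "+", tab$start,
                                   tab$end - 1),
                      subgenome = subgenome_of(tab$chrom),
                      stringsAsFactors = FALSE)
  plus <- genes$strand == "+"
  len <- genes$end - genes$start
  u5 <- 200; u3 <- 200
  features <- rbind(
    data.frame(gene_id = genes$gene_id, type = "exon",
               start = genes$start, end = genes$end),
    data.frame(gene_id = genes$gene_id, type = "five_prime_UTR",
               start = ifelse(plus, genes$start, genes$end - u5),
               end = ifelse(plus, genes$start + u5, genes$end)),
    data.frame(gene_id = genes$gene_id, type = "CDS",
               start = ifelse(plus, genes$start + u5, genes$start + u3),
               end = ifelse(plus, genes$end - u3, genes$end - u5)),
    data.frame(gene_id = genes$gene_id, type = "three_prime_UTR",
               start = ifelse(plus, genes$end - u3, genes$start),
               end = ifelse(plus, genes$end, genes$start + u3)))
  structure(list(genes = genes, features = features), class = "gene_set")
}
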