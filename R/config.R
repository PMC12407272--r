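#' Analysis configuration
#'
#' Bundles every threshold used by the downstream stages. All defaults can
#' be overridden; the object serialises losslessly to YAML.
#'
#' @param tpm_min Expressed-gene TPM threshold (strict >).
#' @param bias_adj_p Adjusted-p threshold for homoeolog bias calls.
#' @param de_fc Fold-change threshold for differential expression
#'   (DEG requires |log2FC| > log2(de_fc)).
#' @param de_fdr FDR threshold for differential expression.
#' @param m6a_ratio Minimum library-normalised IP/input ratio (inclusive).
#' @param m6a_p P-value threshold for m6A peak windows (strict <).
#' @param m6a_diff_fdr FDR threshold for differential m6A.
#' @param m6a_diff_lfc Minimum |delta log2 ratio| for differential m6A.
#' @param proximal_bp Proximal-ACR window upstream of the TSS, bp.
#' @param flank_bp Metaprofile flank width, bp.
#' @param window_genes Fractionation sliding-window size in ancestral
#'   gene slots.
#' @param m6a_bin_bp m6A window size on transcript coordinates, bp.
#' @param seed RNG seed for any stochastic step.
#' @return A list of class \code{subdom_config}.
#' @export
analysis_config <- function(tpm_min = 0.1, bias_adj_p = 0.01, de_fc = 2,
                            de_fdr = 0.05, m6a_ratio = 2, m6a_p = 0.05,
                            m6a_diff_fdr = 0.05, m6a_diff_lfc = 1,
                            proximal_bp = 5000, flank_bp = 2000,
                            window_genes = 100, m6a_bin_bp = 50, seed = 1L) {
  cfg <- list(tpm_min = tpm_min, bias_adj_p = bias_adj_p, de_fc = de_fc,
              de_fdr = de_fdr, m6a_ratio = m6a_ratio, m6a_p = m6a_p,
              m6a_diff_fdr = m6a_diff_fdr, m6a_diff_lfc = m6a_diff_lfc,
              proximal_bp = proximal_bp, flank_bp = flank_bp,
              window_genes = window_genes, m6a_bin_bp = m6a_bin_bp,
              seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), "seed")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(unlist(num) <= 0)) {
    stop("all configuration thresholds must be positive numbers")
  }
  class(cfg) <- "subdom_config"
  cfg
}

#' Read / write configuration as YAML
#'
#' @param path File path.
#' @rdname config_io
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @param config A \code{subdom_config}.
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.subdom_config <- function(x, ...) {
  cat("subdom analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
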