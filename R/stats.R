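#' Statistical test result
#'
#' Lightweight container returned by the package's statistical primitives.
#'
#' @param statistic Test statistic.
#' @param p_value P-value in [0, 1].
#' @param effect Context-defined effect size (log2 fold change, odds ratio,
#'   location shift or fold enrichment).
#' @param method Short description of the procedure.
#' @return An object of class \code{subdom_test}.
#' @keywords internal
new_test_result <- function(statistic, p_value, effect, method) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(
    list(statistic = statistic, p_value = min(p_value, 1),
         effect = effect, method = method),
    class = "subdom_test")
}

#' @export
print.subdom_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, p = %.4g, effect = %.6g\n",
              x$statistic, x$p_value, x$effect))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Returned values are
#' monotone-enforced and reported in the input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as \code{p}.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  # step-up: cumulative minimum of n/i * p_(i) from the largest p downwards
  adj <- pmin(1, cummin(n / seq(n, 1L) * p[o]))[ro]
  adj
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return A \code{subdom_test}; \code{effect} is the sample odds ratio
#'   (\code{Inf} allowed).
#' @examples
#' fisher_exact(1, 9, 11, 3)
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table")
  p <- fisher_p2(a, b, c, d)
  or <- if (b == 0 || c == 0) Inf else (a * d) / (b * c)
  new_test_result(statistic = a, p_value = p, effect = or,
                  method = "Fisher exact test (two-sided, point probability)")
}

# Vectorised two-sided Fisher p for many 2x2 tables; used by the m6A caller.
fisher_p2 <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]          # row 1 total
    m2 <- c[i] + d[i]          # row 2 total
    k <- a[i] + c[i]           # column 1 total
    lo <- max(0, k - m2)
    hi <- min(k, m1)
    x <- lo:hi
    px <- stats::dhyper(x, m1, m2, k)
    pobs <- stats::dhyper(a[i], m1, m2, k)
    p[i] <- min(1, sum(px[px <= pobs * (1 + 1e-7)]))
  }
  p
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test for a location shift between two samples. Uses exact
#' enumeration of the rank-sum distribution when the combined sample size
#' is at most 25 and the data contain no ties; otherwise the normal
#' approximation with tie and continuity corrections. The effect is the
#' Hodges-Lehmann shift (median of all pairwise differences x - y).
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Combined sample size up to which the exact branch is
#'   used (ties force the approximation).
#' @return A \code{subdom_test}; \code{statistic} is the Mann-Whitney U
#'   for \code{x}. For very large samples (over 4e6 pairs) the effect is
#'   the difference of medians rather than the exact Hodges-Lehmann
#'   median of pairwise differences.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))
#' @export
rank_sum_test <- function(x, y, exact_max = 25) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  # Hodges-Lehmann shift; the full pairwise-difference matrix is only
  # materialised for moderate sample sizes, else the difference of
  # medians approximates the shift
  hl <- if (as.numeric(n1) * n2 <= 4e6) {
    stats::median(outer(x, y, "-"))
  } else {
    stats::median(x) - stats::median(y)
  }
  ties <- any(duplicated(all_v))
  if (length(unique(all_v)) == 1L) {
    return(new_test_result(u, 1, 0, "Wilcoxon rank-sum test (degenerate)"))
  }
  if (N <= exact_max && !ties) {
    cnt <- u_count_distribution(n1, n2)    # counts of U = 0..n1*n2
    tot <- sum(cnt)
    pl <- sum(cnt[seq_len(u + 1)]) / tot          # P(U <= u)
    pu <- sum(cnt[(u + 1):(n1 * n2 + 1)]) / tot   # P(U >= u)
    p <- min(1, 2 * min(pl, pu))
    return(new_test_result(u, p, hl, "Wilcoxon rank-sum test (exact)"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(all_v)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    return(new_test_result(u, 1, hl, "Wilcoxon rank-sum test (degenerate)"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test_result(u, p, hl,
                  "Wilcoxon rank-sum test (normal approximation)")
}

# Exact distribution of the Mann-Whitney U statistic: counts of subsets of
# {1..n1+n2} of size n1 by rank sum, shifted to U = 0..n1*n2.
u_count_distribution <- function(n1, n2) {
  N <- n1 + n2
  maxs <- n1 * N               # max possible rank sum for n1 elements
  # dp[j+1, s+1] = number of j-subsets of ranks seen so far with sum s
  dp <- matrix(0, nrow = n1 + 1, ncol = maxs + 1)
  dp[1, 1] <- 1
  for (i in seq_len(N)) {
    jmax <- min(i, n1)
    for (j in jmax:1) {
      s <- which(dp[j, ] > 0) - 1L
      s <- s[s + i <= maxs]
      dp[j + 1, s + i + 1L] <- dp[j + 1, s + i + 1L] + dp[j, s + 1L]
    }
  }
  sums <- which(dp[n1 + 1, ] > 0) - 1L
  umin <- n1 * (n1 + 1) / 2
  cnt <- numeric(n1 * n2 + 1)
  cnt[sums - umin + 1L] <- dp[n1 + 1, sums + 1L]
  cnt
}

#' Hypergeometric enrichment test
#'
#' Upper-tail hypergeometric p-value for over-representation of a gene set
#' among a list of hits, with fold enrichment as the effect.
#'
#' @param hits_in_set Hits belonging to the set.
#' @param set_size Size of the set.
#' @param hits_total Total number of hits.
#' @param universe Size of the universe.
#' @return A \code{subdom_test}; \code{effect} is
#'   \code{(hits_in_set/set_size) / (hits_total/universe)}.
#' @export
hypergeom_enrich <- function(hits_in_set, set_size, hits_total, universe) {
  if (universe <= 0) stop("universe must be positive")
  if (hits_in_set > min(set_size, hits_total)) {
    stop("hits_in_set exceeds set_size or hits_total")
  }
  # upper tail P[X >= hits_in_set], X ~ Hypergeom(universe, hits_total, set_size)
  hi <- min(set_size, hits_total)
  x <- hits_in_set:hi
  logp <- lchoose(hits_total, x) + lchoose(universe - hits_total, set_size - x) -
    lchoose(universe, set_size)
  p <- min(1, sum(exp(logp)))
  eff <- (hits_in_set / set_size) / (hits_total / universe)
  new_test_result(hits_in_set, p, eff, "hypergeometric enrichment (upper tail)")
}

#' Root activity from the TTC reduction assay
#'
#' Dehydrogenase activity of root tissue measured by triphenyl tetrazolium
#' chloride (TTC) reduction. The conventional unit is mg TTC reduced per
#' gram fresh weight per hour, \code{ttc / (weight * hours)}. The
#' alternative literal reading \code{ttc / (weight / hours)} is available
#' via \code{literal = TRUE}; the two coincide at one hour.
#'
#' @param ttc_reduction_mg TTC reduced, mg.
#' @param fresh_weight_g Root fresh weight, g (> 0).
#' @param hours Incubation time, h (> 0).
#' @param literal Use the literal ttc/(weight/time) form.
#' @return Root activity (mg g^-1 h^-1 conventional).
#' @examples
#' root_activity(0.5, 0.25, 1)
#' @export
root_activity <- function(ttc_reduction_mg, fresh_weight_g, hours,
                          literal = FALSE) {
  if (any(fresh_weight_g <= 0) || any(hours <= 0)) {
    stop("fresh weight and time must be positive")
  }
  if (any(ttc_reduction_mg < 0)) stop("TTC reduction must be non-negative")
  if (literal) {
    ttc_reduction_mg / (fresh_weight_g / hours)
  } else {
    ttc_reduction_mg / (fresh_weight_g * hours)
  }
}
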