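# Shared count statistics: median-of-ratios normalisation, a
# negative-binomial conditional test in the style of the classic DESeq
# (Anders & Huber 2010) exact test, Benjamini-Hochberg adjustment, and the
# threshold presets used for genes, DIP enrichment and repeat expression.

#' Median-of-ratios size factors
#'
#' For each sample the size factor is the median, over features with
#' strictly positive counts in every sample, of the ratio of the feature's
#' count to its geometric mean across samples.
#'
#' The factors are rescaled to geometric mean 1, so normalising a matrix
#' by its own size factors is idempotent (the re-normalised matrix has
#' unit factors).
#'
#' @param counts Integer matrix, features x samples.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no feature has positive counts in every sample; ",
         "cannot compute median-of-ratios size factors ",
         "(consider a pseudo-reference fallback)")
  }
  k <- counts[pos, , drop = FALSE]
  loggeo <- rowMeans(log(k))
  s <- apply(k, 2, function(col) exp(median(log(col) - loggeo)))
  s / exp(mean(log(s)))
}

#' Negative-binomial differential test on summed counts
#'
#' Per-feature two-condition test in the spirit of the classic DESeq exact
#' test: counts are normalised by size factors; a per-feature dispersion
#' (squared coefficient of variation of the true concentration) is
#' estimated by method of moments and shared across features through a
#' mean-binned fit; the test conditions the condition-A count sum on the
#' total, modelling each sum as negative binomial with the shared
#' dispersion, and reports a two-sided p-value by doubling the smaller tail
#' (capped at 1).
#'
#' With replicates, the raw variance is the pooled within-condition
#' variance and bins are summarised by their mean (the estimator is
#' unbiased and true effects do not inflate it). Without replicates the
#' two conditions are treated as replicates of each other ("blind"), and
#' bins are summarised by their median so that features carrying real
#' effects do not drag the shared dispersion up.
#'
#' @param counts Integer matrix, features x samples.
#' @param conditions Vector of condition labels, one per sample (exactly
#'   two distinct values). `log2_fold_change` is reported as second
#'   condition over first, in the order of `unique(conditions)` (or factor
#'   levels), i.e. KO/WT when `conditions = c("WT","WT","KO","KO")` with
#'   factor levels WT, KO.
#' @param sf Optional size factors; computed by [size_factors()] when NULL.
#' @param sharing Dispersion sharing across features: `"auto"` (mean-bins
#'   with replicates, median-bins blind), `"none"` (per-feature raw
#'   estimate, floored at zero).
#' @return data.frame: `feature`, `base_mean`, `log2_fold_change`,
#'   `dispersion`, `p_value`, `zero_total` flag.
#' @export
nb_test <- function(counts, conditions, sf = NULL,
                    sharing = c("auto", "none")) {
  sharing <- match.arg(sharing)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%d", seq_len(nrow(counts)))
  }
  conditions <- as.factor(conditions)
  if (nlevels(conditions) != 2L) stop("exactly two conditions are required")
  if (length(conditions) != ncol(counts)) {
    stop("'conditions' must have one label per sample")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  lvl <- levels(conditions)
  ja <- which(conditions == lvl[1]); jb <- which(conditions == lvl[2])
  q <- sweep(counts, 2, sf, "/")
  qbar <- rowMeans(q)
  qa <- rowMeans(q[, ja, drop = FALSE])
  qb <- rowMeans(q[, jb, drop = FALSE])

  replicated <- length(ja) >= 2L || length(jb) >= 2L
  if (replicated) {
    ssq <- 0; df <- 0
    for (jj in list(ja, jb)) {
      if (length(jj) >= 2L) {
        cm <- rowMeans(q[, jj, drop = FALSE])
        ssq <- ssq + rowSums((q[, jj, drop = FALSE] - cm)^2)
        df <- df + (length(jj) - 1L)
      }
    }
    w <- ssq / df
  } else {
    w <- apply(q, 1, var)  # blind: conditions pooled as replicates
  }
  z <- qbar * mean(1 / sf)
  raw_alpha <- ifelse(qbar > 0, (w - z) / qbar^2, NA_real_)
  alpha <- share_dispersion(raw_alpha, qbar, sharing, replicated)

  sa <- sum(sf[ja]); sb <- sum(sf[jb])
  sa2 <- sum(sf[ja]^2); sb2 <- sum(sf[jb]^2)
  ka <- rowSums(counts[, ja, drop = FALSE])
  kb <- rowSums(counts[, jb, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)), function(i) {
    cond_nb_pvalue(ka[i], kb[i], qbar[i], alpha[i], sa, sb, sa2, sb2)
  }, numeric(1))
  data.frame(
    feature = rownames(counts),
    base_mean = qbar,
    log2_fold_change = log2(qb / qa),
    dispersion = alpha,
    p_value = p,
    zero_total = ka + kb == 0L,
    row.names = NULL)
}

# Share per-feature method-of-moments dispersions across features within
# mean-bins; floor at zero (Poisson limit).
share_dispersion <- function(raw_alpha, qbar, sharing, replicated) {
  if (sharing == "none") return(pmax(raw_alpha, 0))
  ok <- is.finite(raw_alpha) & qbar > 0
  n_ok <- sum(ok)
  if (n_ok == 0L) return(rep(0, length(raw_alpha)))
  center <- if (replicated) mean else median
  nbins <- max(1L, min(10L, floor(n_ok / 20L)))
  if (nbins == 1L) {
    shared <- rep(max(0, center(raw_alpha[ok])), length(raw_alpha))
    return(shared)
  }
  br <- unique(quantile(qbar[ok], probs = seq(0, 1, length.out = nbins + 1L)))
  if (length(br) < 3L) {
    return(rep(max(0, center(raw_alpha[ok])), length(raw_alpha)))
  }
  bin <- cut(qbar, br, include.lowest = TRUE)
  per_bin <- tapply(raw_alpha[ok], bin[ok], center)
  per_bin[is.na(per_bin)] <- center(raw_alpha[ok])
  out <- pmax(unname(per_bin[as.integer(bin)]), 0)
  out[is.na(out)] <- max(0, center(raw_alpha[ok]))
  out
}

# Two-sided conditional NB p-value for condition sums ka vs kb given total.
cond_nb_pvalue <- function(ka, kb, qbar, alpha, sa, sb, sa2, sb2) {
  ks <- ka + kb
  if (ks == 0L) return(1)
  mua <- qbar * sa; mub <- qbar * sb
  vara <- mua + alpha * qbar^2 * sa2
  varb <- mub + alpha * qbar^2 * sb2
  a_sup <- 0:ks
  logf <- nb_logpmf(a_sup, mua, vara) + nb_logpmf(ks - a_sup, mub, varb)
  m <- max(logf)
  f <- exp(logf - m)
  f <- f / sum(f)
  p_le <- sum(f[a_sup <= ka])
  p_ge <- sum(f[a_sup >= ka])
  min(1, 2 * min(p_le, p_ge))
}

nb_logpmf <- function(x, mu, v) {
  if (mu <= 0) return(ifelse(x == 0, 0, -Inf))
  if (v > mu) {
    size <- mu^2 / (v - mu)
    stats::dnbinom(x, mu = mu, size = size, log = TRUE)
  } else {
    stats::dpois(x, lambda = mu, log = TRUE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector; missing values propagate
#' with a warning.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (any(is.na(p))) warning("missing p-values propagated unadjusted")
  p.adjust(p, method = "BH")
}

#' Apply the study's significance threshold presets
#'
#' Flags features using the filters applied to each assay: gene
#' expression (fold change > 2, i.e. |log2 FC| > 1, with P < 0.01, split
#' into up/down), DIP enrichment (|log2 FC| > 0.5, P < 0.05) and repeat
#' RNA expression (|log2 FC| > 0.5, P < 0.01). All inequalities are
#' strict, and the raw p-value is used (the adjusted one is carried
#' alongside, never overwritten).
#'
#' @param results data.frame with `log2_fold_change` and `p_value` columns
#'   (e.g. from [nb_test()]).
#' @param preset One of `"genes"`, `"dip"`, `"repeats_rna"`.
#' @return `results` with added `significant` (logical) and `direction`
#'   (`"up"`, `"down"` or NA) columns.
#' @export
apply_thresholds <- function(results, preset = c("genes", "dip",
                                                 "repeats_rna")) {
  preset <- match.arg(preset)
  th <- switch(preset,
    genes = list(lfc = 1, p = 0.01),
    dip = list(lfc = 0.5, p = 0.05),
    repeats_rna = list(lfc = 0.5, p = 0.01))
  lfc <- results$log2_fold_change
  sig <- !is.na(lfc) & !is.na(results$p_value) &
    abs(lfc) > th$lfc & results$p_value < th$p
  results$significant <- sig
  results$direction <- ifelse(sig, ifelse(lfc > 0, "up", "down"),
                              NA_character_)
  results
}
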