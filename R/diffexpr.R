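# Negative-binomial differential expression between the pigmented and
# unpigmented groups: median-of-ratios size factors, method-of-moments
# dispersion with trend shrinkage, a Wald test on closed-form group means,
# Benjamini-Hochberg adjustment, and the two calling regimes (strict for
# lncRNAs: padj <= 0.05 and |log2FC| >= 1.5; relaxed for target-candidate
# genes: p <= 0.01 and |log2FC| >= 1).

#' Median-of-ratios size factors
#'
#' `factor_j = median_i(count_ij / geometric_mean_i)` over features positive
#' in every sample, rescaled to geometric mean 1.
#'
#' @param counts matrix or [count_matrix()] object.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "lnc_counts")) counts$counts else as.matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no feature is positive in all samples; consider a pseudo-reference")
  lg <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, median))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

# Parametric dispersion trend a0 + a1/mu fitted to the per-feature
# method-of-moments estimates (coefficients clamped at 0).
dispersion_trend <- function(alpha_raw, mu) {
  use <- is.finite(alpha_raw) & alpha_raw > 1e-6 & mu > 1
  if (sum(use) < 10) {
    a <- max(median(alpha_raw[is.finite(alpha_raw)]), 1e-8)
    return(function(m) rep(a, length(m)))
  }
  fit <- lm(alpha_raw[use] ~ I(1 / mu[use]))
  a0 <- max(coef(fit)[1], 0)
  a1 <- max(coef(fit)[2], 0)
  function(m) a0 + a1 / pmax(m, 1e-8)
}

#' Per-feature NB dispersion estimates
#'
#' Method of moments on normalized counts, pooled across groups after
#' centering group means: `alpha = max((s^2 - mu) / mu^2, 1e-8)`. With
#' `shrink = TRUE` (default) the raw estimate is averaged with a fitted
#' mean-dispersion trend: `alpha_final = 0.5 * alpha + 0.5 * trend(mu)`.
#'
#' @param cm [count_matrix()] object.
#' @param factors size factors ([size_factors()]).
#' @param shrink logical; apply trend shrinkage.
#' @return named numeric vector of dispersions (floored at 1e-8).
#' @export
estimate_dispersion <- function(cm, factors = size_factors(cm),
                                shrink = TRUE) {
  y <- t(t(cm$counts) / factors)
  g <- cm$group
  centered <- y
  for (lvl in unique(g)) {
    j <- g == lvl
    centered[, j] <- y[, j, drop = FALSE] -
      rowMeans(y[, j, drop = FALSE])
  }
  df <- ncol(y) - length(unique(g))
  s2 <- rowSums(centered^2) / df
  mu <- rowMeans(y)
  alpha_raw <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
  alpha_raw <- pmax(alpha_raw, 1e-8)
  if (!shrink) return(setNames(alpha_raw, rownames(y)))
  trend <- dispersion_trend(alpha_raw, mu)
  setNames(pmax(0.5 * alpha_raw + 0.5 * trend(mu), 1e-8), rownames(y))
}

#' NB Wald test per feature
#'
#' Group means are the closed-form means of normalized counts; a group with
#' all-zero counts receives a pseudo-mean (default 0.5) so fold changes stay
#' bounded. The log2 fold change is pigmented over unpigmented; its standard
#' error comes from the NB variance (`mu + alpha mu^2`) by the delta method,
#' and `z = log2fc / se` is referred to a standard normal (two-sided).
#'
#' @param cm [count_matrix()] object.
#' @param factors size factors.
#' @param alpha per-feature dispersions.
#' @param pseudo_mean pseudo-mean for empty groups.
#' @return data.frame: `feature_id`, `base_mean`, `log2fc`, `se_log2fc`,
#'   `wald_p`, `padj`, `call_strict`, `call_relaxed`.
#' @export
nb_wald_test <- function(cm, factors = size_factors(cm),
                         alpha = estimate_dispersion(cm, factors),
                         pseudo_mean = 0.5) {
  y <- t(t(cm$counts) / factors)
  gp <- cm$group == "pigmented"
  n_p <- sum(gp); n_u <- sum(!gp)
  m_p <- rowMeans(y[, gp, drop = FALSE])
  m_u <- rowMeans(y[, !gp, drop = FALSE])
  both_zero <- m_p == 0 & m_u == 0
  mp <- ifelse(m_p == 0, pseudo_mean, m_p)
  mu_ <- ifelse(m_u == 0, pseudo_mean, m_u)
  lfc <- log2(mp / mu_)
  sf_p <- factors[gp]; sf_u <- factors[!gp]
  v_p <- (mp * sum(1 / sf_p) + alpha * mp^2 * n_p) / n_p^2
  v_u <- (mu_ * sum(1 / sf_u) + alpha * mu_^2 * n_u) / n_u^2
  se <- sqrt(v_p / mp^2 + v_u / mu_^2) / log(2)
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))
  lfc[both_zero] <- 0
  p[both_zero] <- 1
  se[both_zero] <- NA_real_
  padj <- bh_adjust(p)
  data.frame(feature_id = rownames(y),
             base_mean = rowMeans(y),
             log2fc = lfc, se_log2fc = se, wald_p = p, padj = padj,
             call_strict = padj <= 0.05 & abs(lfc) >= 1.5,
             call_relaxed = p <= 0.01 & abs(lfc) >= 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")` behind this
#' surface); stable under input order.
#'
#' @param p numeric p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Call differentially expressed features
#'
#' `strict`: `padj <= 0.05` and `|log2fc| >= 1.5` (lncRNA regime);
#' `relaxed`: `p <= 0.01` and `|log2fc| >= 1` (target-candidate regime).
#' Boundaries inclusive. Direction is the sign of the pigmented-over-
#' unpigmented fold change.
#'
#' @param res [nb_wald_test()] results.
#' @param mode `"strict"` or `"relaxed"`.
#' @return list with `up`, `down` and `all` feature ids.
#' @export
call_de <- function(res, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  hit <- if (mode == "strict") res$padj <= 0.05 & abs(res$log2fc) >= 1.5
         else res$wald_p <= 0.01 & abs(res$log2fc) >= 1
  hit[is.na(hit)] <- FALSE
  list(up = res$feature_id[hit & res$log2fc > 0],
       down = res$feature_id[hit & res$log2fc < 0],
       all = res$feature_id[hit])
}
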