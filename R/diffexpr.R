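#' Median-of-ratios size factors
#'
#' Standard median-of-ratios normalization for a count matrix: each sample's
#' factor is the median over genes of the ratio between its count and the
#' gene's geometric mean across samples; only genes with a positive geometric
#' mean (nonzero in every sample) enter the median.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @return named numeric vector of strictly positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("cannot normalize an all-zero count matrix")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no gene has nonzero counts in every sample; cannot normalize")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(col) - log_geo[use]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

#' Per-gene negative-binomial dispersion (method of moments)
#'
#' Under the NB variance model `var = mu + d mu^2`, the raw per-gene estimate
#' is `(v - m * a) / m^2`, where `v` is the within-condition variance of
#' normalized counts pooled across the two conditions (condition means
#' removed), `m` the overall mean of normalized counts and `a` the mean
#' reciprocal size factor (the Poisson term of a normalized count is
#' `mu / sf`). Negative raw estimates are floored.
#'
#' With few replicates the raw estimate is noisy, which makes a plug-in Wald
#' test anti-conservative. The default `moderate = TRUE` therefore floors
#' every gene at the across-gene median of the raw estimates — a conservative
#' sharing step that assumes no mean-dispersion trend (none is fitted).
#' `moderate = FALSE` keeps the literal per-gene estimate (floored at
#' `min_disp` only).
#'
#' @param counts count matrix, genes x samples.
#' @param conditions character/factor of length `ncol(counts)` with exactly
#'   two levels.
#' @param size_factors positive per-sample factors; computed if `NULL`.
#' @param min_disp small positive floor.
#' @param moderate floor per-gene estimates at the across-gene median raw
#'   estimate (default).
#' @return named numeric vector of dispersions (>= `min_disp`).
#' @export
estimate_dispersion <- function(counts, conditions, size_factors = NULL,
                                min_disp = 1e-8, moderate = TRUE) {
  counts <- as.matrix(counts)
  conditions <- as.character(conditions)
  lv <- unique(conditions)
  if (length(lv) != 2) stop("exactly two conditions are required")
  if (min(table(conditions)) < 2)
    stop("at least 2 replicates per condition are required to estimate dispersion")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  q <- sweep(counts, 2, size_factors, "/")
  a <- mean(1 / size_factors)
  v <- 0; df <- 0; m <- 0
  for (cond in lv) {
    qc <- q[, conditions == cond, drop = FALSE]
    nc <- ncol(qc)
    v <- v + apply(qc, 1, stats::var) * (nc - 1)
    df <- df + nc - 1
    m <- m + rowMeans(qc) / 2
  }
  v <- v / df
  raw <- ifelse(m > 0, (v - m * a) / m^2, 0)
  floor_d <- min_disp
  if (moderate) floor_d <- max(min_disp, stats::median(raw[m > 0]))
  d <- pmax(raw, floor_d)
  stats::setNames(d, rownames(counts))
}

#' Convert a log2 fold change to the signed linear fold-change convention
#'
#' Downregulation is reported as a negative magnitude rather than a ratio
#' below one: `fc = 2^lfc` for `lfc >= 0` and `fc = -2^(-lfc)` for `lfc < 0`,
#' so a gene four-fold lower in the mutant has `fc = -4` and `|fc| >= 1`
#' always holds.
#'
#' @param lfc numeric log2 fold change(s).
#' @return signed fold change(s).
#' @export
lfc_to_fc <- function(lfc) ifelse(lfc >= 0, 2^lfc, -2^(-lfc))

#' Convert a signed fold change back to a log2 fold change
#'
#' Inverse of [lfc_to_fc()]; requires `|fc| >= 1`.
#'
#' @param fc signed fold change(s), `|fc| >= 1`.
#' @return log2 fold change(s).
#' @export
fc_to_lfc <- function(fc) {
  if (any(abs(fc) < 1)) stop("signed fold changes must have magnitude >= 1")
  sign(fc) * log2(abs(fc))
}

#' Negative-binomial Wald test for two conditions
#'
#' Per gene, the log2 fold change of the mutant over the wild-type mean of
#' normalized counts (a pseudocount is added to both means), a delta-method
#' standard error under the NB variance model (the pseudocount-stabilized
#' means enter the variance as well, so all-zero conditions do not produce a
#' zero standard error), the Wald statistic and a two-sided p value from the
#' standard normal. Genes with zero counts in every sample are flagged
#' untested (`tested = FALSE`, p value 1) and should be excluded from
#' multiple-testing adjustment.
#'
#' @param counts count matrix, genes x samples.
#' @param conditions per-sample labels; must contain `mutant_label` and
#'   `wildtype_label`.
#' @param size_factors,dispersions optional precomputed values (see
#'   [estimate_size_factors()], [estimate_dispersion()]).
#' @param pseudocount added to normalized condition means (default 0.5).
#' @param mutant_label,wildtype_label the numerator and denominator
#'   conditions; the contrast is always mutant over wild type.
#' @return data.frame with one row per gene: `gene_id`, `base_mean`,
#'   `log2fc`, `fc` (signed convention), `se`, `stat`, `pvalue`, `tested`.
#' @export
wald_test <- function(counts, conditions, size_factors = NULL,
                      dispersions = NULL, pseudocount = 0.5,
                      mutant_label = "mutant", wildtype_label = "wildtype") {
  counts <- as.matrix(counts)
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == ncol(counts))
  for (lab in c(mutant_label, wildtype_label)) {
    if (sum(conditions == lab) < 2)
      stop("condition '", lab, "' needs at least 2 replicates")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, conditions, size_factors)
  q <- sweep(counts, 2, size_factors, "/")

  cond_stats <- function(lab) {
    qc <- q[, conditions == lab, drop = FALSE]
    list(m = rowMeans(qc), n = ncol(qc),
         a = mean(1 / size_factors[conditions == lab]))
  }
  mut <- cond_stats(mutant_label)
  wt <- cond_stats(wildtype_label)

  m_mut <- mut$m + pseudocount
  m_wt <- wt$m + pseudocount
  lfc <- log2(m_mut) - log2(m_wt)
  # delta method on log2 of a condition mean of normalized NB counts
  v_mut <- (m_mut * mut$a + dispersions * m_mut^2) / mut$n
  v_wt <- (m_wt * wt$a + dispersions * m_wt^2) / wt$n
  se <- sqrt(v_mut / m_mut^2 + v_wt / m_wt^2) / log(2)
  stat <- lfc / se
  pvalue <- 2 * stats::pnorm(-abs(stat))

  tested <- rowSums(counts) > 0
  lfc[!tested] <- 0
  stat[!tested] <- 0
  pvalue[!tested] <- 1

  data.frame(
    gene_id = rownames(counts),
    base_mean = rowMeans(q),
    log2fc = lfc,
    fc = lfc_to_fc(lfc),
    se = se, stat = stat, pvalue = pvalue,
    tested = tested,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p values ascending, takes `adj_(i) = min_(j >= i) p_(j) * m / j`
#' capped at 1, and returns the adjusted values in the input order. `NA`
#' inputs stay `NA` and do not count toward the family size `m`.
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs allowed).
#' @return adjusted p values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  adj <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m == 0) return(adj)
  ord <- ok[order(pvalues[ok])]
  stepped <- pvalues[ord] * m / seq_len(m)
  adj[ord] <- pmin(rev(cummin(rev(stepped))), 1)
  adj
}

#' Run the full differential-expression stage
#'
#' Normalization, dispersion estimation, Wald test and BH adjustment in one
#' call. Untested genes (all-zero) are excluded from the BH family and get
#' `padj = NA`.
#'
#' @inheritParams wald_test
#' @param moderate_dispersion passed to [estimate_dispersion()].
#' @return data.frame of per-gene records: `gene_id`, `base_mean`, `log2fc`,
#'   `fc`, `se`, `stat`, `pvalue`, `padj`, `tested`.
#' @export
run_de <- function(counts, conditions = NULL, pseudocount = 0.5,
                   mutant_label = "mutant", wildtype_label = "wildtype",
                   moderate_dispersion = TRUE) {
  if (is.null(conditions)) conditions <- attr(counts, "conditions")
  if (is.null(conditions)) stop("per-sample condition labels are required")
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, conditions, sf,
                              moderate = moderate_dispersion)
  de <- wald_test(counts, conditions, sf, disp, pseudocount,
                  mutant_label, wildtype_label)
  de$padj <- NA_real_
  de$padj[de$tested] <- bh_adjust(de$pvalue[de$tested])
  de
}
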