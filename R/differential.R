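#' Contrast two genotype x condition groups
#'
#' Per-probe linear fold change, mean expression value and pooled-variance
#' (equal-SD) two-tailed t-test between two sample groups of a log2
#' expression matrix, with Benjamini-Hochberg adjustment across all probes
#' of the contrast.
#'
#' Fold change is reported on the linear scale, `FC = 2^(mean_A - mean_B)`,
#' while means are on the log2 scale of the input. MEV is the per-probe mean
#' of the two group means (log2 units), the x-axis of FC-vs-MEV plots. The
#' t statistic uses the pooled variance with `n_A + n_B - 2` degrees of
#' freedom. Probes with zero pooled variance get `p_raw = 1` when the group
#' means are equal and `p_raw = 0` otherwise, and are flagged in the
#' `zero_variance` column.
#'
#' @param em an ExpressionMatrix with a joined sample sheet.
#' @param group_a,group_b group labels such as `"WT_M1"` or
#'   `c("WT", "M1")`; group A is the numerator of the fold change.
#' @param label optional contrast label; defaults to `"A_vs_B"`.
#' @return a data.frame of class `"contrast_result"` with columns
#'   `probe_id`, `gene_symbol`, `mean_log2_a`, `mean_log2_b`, `mev`, `fc`,
#'   `p_raw`, `p_adj`, `zero_variance`, and attributes `label`, `group_a`,
#'   `group_b`, `n_a`, `n_b`.
#' @export
contrast <- function(em, group_a, group_b, label = NULL) {
  if (is.null(em$samples)) stop2("no sample sheet joined; see join_sample_sheet()")
  ia <- group_samples(em, group_a)
  ib <- group_samples(em, group_b)
  if (length(intersect(ia, ib))) stop2("contrast groups must be disjoint")
  na <- length(ia); nb <- length(ib)
  if (na < 2L || nb < 2L)
    stop2(sprintf("each group needs >= 2 samples to compute a p-value (got %d vs %d)",
                  na, nb))
  A <- em$E[, ia, drop = FALSE]
  B <- em$E[, ib, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1L)
  vb <- rowSums((B - mb)^2) / (nb - 1L)
  df <- na + nb - 2L
  s2 <- ((na - 1L) * va + (nb - 1L) * vb) / df
  se <- sqrt(s2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- se == 0
  if (any(zero_var)) {
    p[zero_var] <- ifelse(ma[zero_var] == mb[zero_var], 1, 0)
    message(sum(zero_var), " probe(s) with zero pooled variance flagged")
  }
  res <- data.frame(probe_id = em$genes$probe_id,
                    gene_symbol = em$genes$gene_symbol,
                    mean_log2_a = ma, mean_log2_b = mb,
                    mev = (ma + mb) / 2,
                    fc = 2^(ma - mb),
                    p_raw = p,
                    p_adj = adjust_bh(p),
                    zero_variance = zero_var,
                    row.names = NULL)
  structure(res,
            class = c("contrast_result", "data.frame"),
            label = label %||% paste0(group_label(group_a), "_vs_",
                                      group_label(group_b)),
            group_a = group_label(group_a), group_b = group_label(group_b),
            n_a = na, n_b = nb)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values sorted ascending are
#' scaled by `m/i`, a cumulative minimum is taken from the largest rank
#' down, values are capped at 1 and returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop2("p-values must be numeric in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Call an up/down signature from a contrast
#'
#' Genes with `FC >= up_fc` (and p below `alpha`) form the up signature;
#' genes with `FC <= down_fc` form the down signature. Threshold
#' comparisons are inclusive by default. The p filter uses BH-adjusted
#' p-values by default; `p_value = "raw"` switches to unadjusted ones.
#'
#' @param cr a [contrast()] result.
#' @param up_fc,down_fc linear fold-change thresholds,
#'   `up_fc > 1 > down_fc > 0`.
#' @param alpha significance level for the p filter.
#' @param p_value `"adjusted"` or `"raw"`.
#' @param inclusive logical; if FALSE the FC comparisons are strict.
#' @return an object of class `"signature"`: list with `up` and `down`
#'   probe-matched [gene_set()]s, the thresholds used and counts.
#' @export
call_signature <- function(cr, up_fc = 2, down_fc = 0.5, alpha = 0.05,
                           p_value = c("adjusted", "raw"), inclusive = TRUE) {
  p_value <- match.arg(p_value)
  assert_scalar_number(up_fc, "up_fc"); assert_scalar_number(down_fc, "down_fc")
  if (!(up_fc > 1 && 1 > down_fc && down_fc > 0))
    stop2("need up_fc > 1 > down_fc > 0")
  p <- if (p_value == "adjusted") cr$p_adj else cr$p_raw
  up_sel <- if (inclusive) cr$fc >= up_fc else cr$fc > up_fc
  dn_sel <- if (inclusive) cr$fc <= down_fc else cr$fc < down_fc
  up <- up_sel & p < alpha
  dn <- dn_sel & p < alpha
  structure(
    list(up = gene_set(cr$probe_id[up], name = "signature_up",
                       direction = "up", match = "probe"),
         down = gene_set(cr$probe_id[dn], name = "signature_down",
                         direction = "down", match = "probe"),
         up_fc = up_fc, down_fc = down_fc, alpha = alpha,
         p_value = p_value, inclusive = inclusive,
         n_up = sum(up), n_down = sum(dn),
         contrast = attr(cr, "label")),
    class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf(
    "signature from %s: %d up (FC %s %s), %d down (FC %s %s), %s p < %g\n",
    x$contrast %||% "<contrast>",
    x$n_up, if (x$inclusive) ">=" else ">", format(x$up_fc),
    x$n_down, if (x$inclusive) "<=" else "<", format(x$down_fc),
    x$p_value, x$alpha))
  invisible(x)
}

#' Write a contrast result as TSV
#' @param cr a contrast_result.
#' @param path output path.
#' @export
write_contrast <- function(cr, path) {
  utils::write.table(as.data.frame(cr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
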