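#' Construct a Ct table
#'
#' Long-format qPCR threshold-cycle data: one row per (sample, gene)
#' measurement, with a designated reference gene (e.g. Hprt for mRNA,
#' sno202 for small RNA) that must be present for every sample. An
#' optional `group` column carries condition labels for group-level
#' calibration and percent-of-condition reporting.
#'
#' @param data data.frame with columns `sample_id`, `gene`, `ct` and
#'   optionally `group`.
#' @param reference_gene name of the reference gene.
#' @return data.frame of class `"ct_table"` with attribute
#'   `reference_gene`.
#' @export
ct_table <- function(data, reference_gene) {
  need <- c("sample_id", "gene", "ct")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop2("Ct table missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(data$ct) || any(!is.finite(data$ct)) || any(data$ct <= 0))
    stop2("Ct values must be positive finite numbers")
  if (anyDuplicated(data[c("sample_id", "gene")]))
    stop2("duplicate (sample_id, gene) measurement")
  samples <- unique(data$sample_id)
  have_ref <- unique(data$sample_id[data$gene == reference_gene])
  miss_ref <- setdiff(samples, have_ref)
  if (length(miss_ref))
    stop2("reference gene '", reference_gene, "' missing for sample(s): ",
          paste(miss_ref, collapse = ", "))
  structure(as.data.frame(data), class = c("ct_table", "data.frame"),
            reference_gene = reference_gene)
}

#' Read a Ct table from CSV
#'
#' @param path CSV with columns `sample_id`, `gene`, `ct` and optionally
#'   `group`.
#' @inheritParams ct_table
#' @export
read_ct_table <- function(path, reference_gene) {
  if (!file.exists(path)) stop2("file not found: ", path)
  ct_table(utils::read.csv(path, stringsAsFactors = FALSE), reference_gene)
}

ct_lookup <- function(ct, gene) {
  rows <- ct[ct$gene == gene, , drop = FALSE]
  stats::setNames(rows$ct, rows$sample_id)
}

calibrator_samples <- function(ct, calibrator) {
  samples <- unique(ct$sample_id)
  if (all(calibrator %in% samples)) return(calibrator)
  if (!is.null(ct$group)) {
    hit <- unique(ct$sample_id[ct$group %in% calibrator])
    if (length(hit)) return(hit)
  }
  stop2("calibrator '", paste(calibrator, collapse = ", "),
        "' matches no sample id or group label")
}

#' Comparative-Ct (delta-delta-Ct) relative quantification
#'
#' `RQ = 2^-ddCt` with `dCt = Ct_target - Ct_reference` per sample and
#' `ddCt = dCt_sample - mean(dCt)` over the calibrator sample(s). With a
#' group calibrator the mean dCt is used, which is the geometric-mean
#' calibration on the linear scale. The calibrator's (geometric mean) RQ
#' is 1 by construction. Valid when target and reference amplification
#' efficiencies are comparable; otherwise use
#' [standard_curve_quantify()].
#'
#' @param ct a [ct_table()].
#' @param target gene to quantify.
#' @param calibrator a sample id (or ids), or a group label when the table
#'   has a `group` column.
#' @return data.frame `sample_id`, `group` (if present), `dct`, `ddct`,
#'   `rq`.
#' @export
ddct_quantify <- function(ct, target, calibrator) {
  ref <- ct_lookup(ct, attr(ct, "reference_gene"))
  tgt <- ct_lookup(ct, target)
  if (!length(tgt)) stop2("no Ct rows for target gene '", target, "'")
  miss <- setdiff(names(tgt), names(ref))
  if (length(miss))
    stop2("missing reference Ct for sample(s): ", paste(miss, collapse = ", "))
  dct <- tgt - ref[names(tgt)]
  cal <- calibrator_samples(ct, calibrator)
  cal <- intersect(cal, names(dct))
  if (!length(cal)) stop2("calibrator sample(s) have no Ct for the target gene")
  ddct <- dct - mean(dct[cal])
  out <- data.frame(sample_id = names(dct), dct = unname(dct),
                    ddct = unname(ddct), rq = unname(2^-ddct))
  if (!is.null(ct$group))
    out$group <- ct$group[match(out$sample_id, ct$sample_id)]
  out
}

#' Fit a qPCR standard curve
#'
#' Linear regression of Ct on log10 input quantity over a dilution series.
#' Amplification efficiency is derived from the slope as
#' `E = 10^(-1/slope) - 1`; a slope of -3.3219 corresponds to 100%
#' efficiency (perfect doubling per cycle).
#'
#' @param log10_quantity log10 of input quantities.
#' @param ct measured Ct values.
#' @return object of class `"standard_curve"`: list with `slope`,
#'   `intercept`, `efficiency`, `r_squared` and the Ct range of the
#'   points.
#' @export
standard_curve <- function(log10_quantity, ct) {
  if (length(log10_quantity) != length(ct) || length(ct) < 3L)
    stop2("need >= 3 paired (log10 quantity, Ct) points")
  fit <- stats::lm(ct ~ log10_quantity)
  slope <- stats::coef(fit)[[2L]]
  if (slope >= 0) stop2("standard-curve slope must be negative")
  r2 <- stats::cor(log10_quantity, ct)^2
  structure(list(slope = slope, intercept = stats::coef(fit)[[1L]],
                 efficiency = 10^(-1 / slope) - 1, r_squared = r2,
                 ct_range = range(ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: Ct = %.4g + %.4g * log10(q), efficiency %.1f%%\n",
              x$intercept, x$slope, 100 * x$efficiency))
  invisible(x)
}

#' Are two amplification efficiencies comparable?
#'
#' Comparable means the absolute efficiency difference is below `tol`
#' (default 5 percentage points); the comparative-Ct method is appropriate
#' then, the standard-curve method otherwise.
#'
#' @param curve_a,curve_b [standard_curve()] fits.
#' @param tol maximum efficiency difference (fraction).
#' @export
efficiencies_comparable <- function(curve_a, curve_b, tol = 0.05) {
  abs(curve_a$efficiency - curve_b$efficiency) < tol
}

#' Standard-curve relative quantification
#'
#' Interpolates each Ct on its gene's standard curve,
#' `quantity = 10^((Ct - intercept)/slope)`, and divides the target
#' quantity by the reference-gene quantity per sample. With a calibrator,
#' ratios are normalized by the geometric mean calibrator ratio, matching
#' the comparative-Ct convention; at 100% efficiency on both curves the
#' two methods agree to numerical precision. Ct values falling more than
#' `extrapolation_margin` cycles outside the curve's Ct range are flagged.
#'
#' @param ct a [ct_table()].
#' @param curves named list of [standard_curve()]s, one per gene quantified
#'   (including the reference gene).
#' @param target gene to quantify.
#' @param calibrator optional calibrator sample id(s) or group label.
#' @param extrapolation_margin cycles of tolerated extrapolation.
#' @return data.frame `sample_id`, `quantity_target`, `quantity_ref`,
#'   `rq`, `extrapolated` (and `group` if present).
#' @export
standard_curve_quantify <- function(ct, curves, target, calibrator = NULL,
                                    extrapolation_margin = 1) {
  ref_gene <- attr(ct, "reference_gene")
  for (g in c(target, ref_gene))
    if (is.null(curves[[g]])) stop2("no standard curve for gene '", g, "'")
  quantify <- function(gene) {
    cv <- curves[[gene]]
    cts <- ct_lookup(ct, gene)
    q <- 10^((cts - cv$intercept) / cv$slope)
    outside <- cts < cv$ct_range[1L] - extrapolation_margin |
      cts > cv$ct_range[2L] + extrapolation_margin
    list(q = q, outside = outside)
  }
  tq <- quantify(target)
  rq_ <- quantify(ref_gene)
  samples <- names(tq$q)
  miss <- setdiff(samples, names(rq_$q))
  if (length(miss))
    stop2("missing reference Ct for sample(s): ", paste(miss, collapse = ", "))
  ratio <- tq$q / rq_$q[samples]
  extrapolated <- tq$outside | rq_$outside[samples]
  if (any(extrapolated))
    warning("Ct outside standard-curve range for sample(s): ",
            paste(samples[extrapolated], collapse = ", "), call. = FALSE)
  if (!is.null(calibrator)) {
    cal <- intersect(calibrator_samples(ct, calibrator), samples)
    if (!length(cal)) stop2("calibrator sample(s) not quantified for the target")
    ratio <- ratio / gmean(ratio[cal])
  }
  out <- data.frame(sample_id = samples,
                    quantity_target = unname(tq$q),
                    quantity_ref = unname(rq_$q[samples]),
                    rq = unname(ratio),
                    extrapolated = unname(extrapolated))
  if (!is.null(ct$group))
    out$group <- ct$group[match(out$sample_id, ct$sample_id)]
  out
}

#' Express group means as a percentage of a reference condition
#'
#' Scales per-group mean relative quantities so the reference condition's
#' mean equals 100; the SEM is propagated by the same scale factor
#' (figure convention "percentage of the WT M1 condition +/- SEM").
#'
#' @param rq numeric vector of relative quantities.
#' @param group group/condition label per value.
#' @param reference the reference condition label.
#' @return data.frame `group`, `n`, `percent`, `sem`.
#' @export
percent_of_condition <- function(rq, group, reference) {
  if (length(rq) != length(group)) stop2("'rq' and 'group' must be aligned")
  if (!reference %in% group) stop2("reference condition '", reference,
                                   "' not present")
  means <- tapply(rq, group, mean)
  if (means[[reference]] == 0) stop2("reference condition mean is zero")
  scale <- 100 / means[[reference]]
  sems <- tapply(rq, group, function(v)
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  ns <- tapply(rq, group, length)
  data.frame(group = names(means), n = as.integer(ns),
             percent = as.numeric(means) * scale,
             sem = as.numeric(sems) * scale, row.names = NULL)
}
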