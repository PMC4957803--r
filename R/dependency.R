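#' Partition a wild-type signature by its knockout behaviour
#'
#' The core dependency computation: each signature gene is labelled by how
#' its activation response survives loss of the microRNA.
#'
#' * `dependent` - the KO fold change falls strictly inside the
#'   (`down_fc`, `up_fc`) band: the gene no longer responds without the
#'   microRNA. Strict bounds are the complement of the inclusive signature
#'   call.
#' * `attenuated` - the KO fold change is still beyond the band but the
#'   response is blunted: `FC_KO / FC_WT < 1` for up genes,
#'   `> 1` for down genes.
#' * `independent` - everything else (response as strong or stronger in KO).
#'
#' Summary percentages are reported per direction and pooled: the overall
#' percentage is the unweighted fraction of dependent genes over the union
#' of the up and down signatures.
#'
#' @param signature a [call_signature()] result on the WT contrast.
#' @param fc_wt [contrast()] result for WT-M1 vs WT-M0.
#' @param fc_ko [contrast()] result for KO-M1 vs KO-M0.
#' @param up_fc,down_fc fold-change band edges; default to the signature's
#'   own thresholds.
#' @return a data.frame of class `"dependency_partition"` with columns
#'   `probe_id`, `gene_symbol`, `direction`, `fc_wt`, `fc_ko`, `ratio`
#'   (`fc_ko/fc_wt`), `label`, and a `summary` attribute carrying
#'   `pct_up_dependent`, `pct_down_dependent`, `pct_overall_dependent` and
#'   the label counts.
#' @export
classify_dependency <- function(signature, fc_wt, fc_ko,
                                up_fc = signature$up_fc,
                                down_fc = signature$down_fc) {
  per_dir <- function(gs, direction) {
    if (!length(gs$members)) return(NULL)
    iw <- match_gene_set(fc_wt, gs)
    ik <- match_gene_set(fc_ko, gs)
    data.frame(probe_id = fc_wt$probe_id[iw],
               gene_symbol = fc_wt$gene_symbol[iw],
               direction = direction,
               fc_wt = fc_wt$fc[iw],
               fc_ko = fc_ko$fc[ik])
  }
  tab <- rbind(per_dir(signature$up, "up"), per_dir(signature$down, "down"))
  if (is.null(tab))
    tab <- data.frame(probe_id = character(), gene_symbol = character(),
                      direction = character(), fc_wt = numeric(),
                      fc_ko = numeric())
  tab$ratio <- tab$fc_ko / tab$fc_wt
  in_band <- tab$fc_ko > down_fc & tab$fc_ko < up_fc
  attenuated <- !in_band &
    ifelse(tab$direction == "up", tab$ratio < 1, tab$ratio > 1)
  tab$label <- ifelse(in_band, "dependent",
                      ifelse(attenuated, "attenuated", "independent"))
  pct <- function(sel) if (any(sel)) 100 * mean(tab$label[sel] == "dependent") else NA_real_
  summary <- list(
    n_up = sum(tab$direction == "up"),
    n_down = sum(tab$direction == "down"),
    counts = table(factor(tab$label,
                          levels = c("dependent", "attenuated", "independent"))),
    pct_up_dependent = pct(tab$direction == "up"),
    pct_down_dependent = pct(tab$direction == "down"),
    pct_overall_dependent = if (nrow(tab))
      100 * mean(tab$label == "dependent") else NA_real_)
  structure(tab, class = c("dependency_partition", "data.frame"),
            summary = summary, up_fc = up_fc, down_fc = down_fc)
}

#' @export
print.dependency_partition <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("dependency partition: %d up + %d down signature genes\n",
              s$n_up, s$n_down))
  cat(sprintf("  dependent %d | attenuated %d | independent %d\n",
              s$counts[["dependent"]], s$counts[["attenuated"]],
              s$counts[["independent"]]))
  cat(sprintf("  %% dependent: up %.1f, down %.1f, overall %.1f\n",
              s$pct_up_dependent, s$pct_down_dependent,
              s$pct_overall_dependent))
  invisible(x)
}

#' Compile the microRNA-affected gene list
#'
#' Union of two criteria, applied symmetrically to the up (`>= up_fc`) and
#' down (`<= down_fc`) directions:
#'
#' 1. responds in WT (`FC_WT` beyond a threshold) but not in KO
#'    (`FC_KO` inside the band), and
#' 2. differs directly between the activated genotypes
#'    (`FC_cross` = WT-M1 vs KO-M1 beyond a threshold, either direction).
#'
#' @param fc_wt,fc_ko,fc_cross [contrast()] results sharing one probe
#'   universe: WT-M1 vs WT-M0, KO-M1 vs KO-M0 and the cross-genotype
#'   contrast between activated samples.
#' @param up_fc,down_fc fold-change thresholds.
#' @return a probe-matched [gene_set()] with a `provenance` attribute
#'   (data.frame `probe_id`, `criterion` in `wt_not_ko` / `cross` /
#'   `both`).
#' @export
compile_affected_list <- function(fc_wt, fc_ko, fc_cross,
                                  up_fc = 2, down_fc = 0.5) {
  if (!identical(fc_wt$probe_id, fc_ko$probe_id) ||
      !identical(fc_wt$probe_id, fc_cross$probe_id))
    stop2("contrasts must share an identical probe universe")
  crit1 <- (fc_wt$fc >= up_fc & fc_ko$fc < up_fc) |
    (fc_wt$fc <= down_fc & fc_ko$fc > down_fc)
  crit2 <- fc_cross$fc >= up_fc | fc_cross$fc <= down_fc
  sel <- crit1 | crit2
  prov <- ifelse(crit1 & crit2, "both", ifelse(crit1, "wt_not_ko", "cross"))
  gs <- gene_set(fc_wt$probe_id[sel], name = "mir_affected",
                 direction = "none", match = "probe")
  attr(gs, "provenance") <- data.frame(probe_id = fc_wt$probe_id[sel],
                                       criterion = prov[sel])
  gs
}

#' Fit a power-law trend to paired fold changes
#'
#' Ordinary least squares of `log2(fc_ko)` on `log2(fc_wt)`, summarising
#' how knockout responses scale with wild-type responses as
#' `FC_KO = a * FC_WT^b`. `b = 1, a = 1` is the identity line (responses
#' preserved); `b < 1` is a global dampening of response magnitudes. The
#' parameters are invariant to the logarithm base used.
#'
#' @param fc_wt,fc_ko paired vectors of linear fold changes, all positive.
#' @return an object of class `"power_law_fit"`: list with `a`
#'   (multiplier, `2^intercept`), `b` (exponent, the slope), `r_squared`
#'   of the log-log regression, and `n`.
#' @export
fit_fcfc_trend <- function(fc_wt, fc_ko) {
  if (length(fc_wt) != length(fc_ko)) stop2("fold-change vectors must be paired")
  if (length(fc_wt) < 3L) stop2("need at least 3 points to fit a trend")
  if (any(!is.finite(fc_wt)) || any(!is.finite(fc_ko)) ||
      any(fc_wt <= 0) || any(fc_ko <= 0))
    stop2("fold changes must be finite and positive")
  x <- log2(fc_wt); y <- log2(fc_ko)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(a = 2^co[[1L]], b = co[[2L]],
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n = length(x)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law trend: y = %.4g * x^%.4g (R^2 = %.4g, n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' Report a marker panel on the FC-vs-FC plane
#'
#' For each panel gene: its WT and KO fold changes, whether it lies above
#' the `y = x` line (`fc_ko > fc_wt`, i.e. less suppressed / more induced
#' in the knockout), and its dependency label when it belongs to the
#' partitioned signature. Used e.g. for alternative-activation (M2) marker
#' panels whose suppression under inflammatory stimulation is blunted in
#' the knockout.
#'
#' @param panel a [gene_set()] (symbol- or probe-matched).
#' @param fc_wt,fc_ko [contrast()] results.
#' @param partition optional [classify_dependency()] result.
#' @return data.frame with one row per panel gene found; errors if no
#'   panel gene is present in the contrasts.
#' @export
marker_panel_report <- function(panel, fc_wt, fc_ko, partition = NULL) {
  if (!length(panel$members)) stop2("empty marker panel")
  iw <- match_gene_set(fc_wt, panel, allow_missing = TRUE)
  if (!length(iw))
    stop2("no panel gene found in contrasts: ",
          paste(panel$members, collapse = ", "))
  probes <- fc_wt$probe_id[iw]
  ik <- match(probes, fc_ko$probe_id)
  if (anyNA(ik)) stop2("panel probe(s) missing from the KO contrast")
  out <- data.frame(probe_id = probes,
                    gene_symbol = fc_wt$gene_symbol[iw],
                    fc_wt = fc_wt$fc[iw],
                    fc_ko = fc_ko$fc[ik])
  out$above_line <- out$fc_ko > out$fc_wt
  out$dependency <- if (!is.null(partition))
    partition$label[match(probes, partition$probe_id)] else NA_character_
  out
}
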