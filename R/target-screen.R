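RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

rna_normalize <- function(x, what = "sequence") {
  s <- chartr("tT", "uU", toupper(x))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(RNA_COMPLEMENT))
  if (length(bad))
    stop2(sprintf("invalid character '%s' at position %d of %s",
                  chars[bad[1L]], bad[1L], what))
  s
}

rna_revcomp <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(rev(RNA_COMPLEMENT[chars]), collapse = "")
}

#' Construct a mature microRNA
#'
#' Holds the mature sequence (5' to 3', RNA alphabet; T is accepted and
#' converted to U) and its seed, nucleotides 2-8, which drives canonical
#' 3'UTR site recognition.
#'
#' @param name microRNA name, e.g. `"miR-155-5p"`.
#' @param sequence mature sequence, length >= 8.
#' @return an object of class `"MatureMiRNA"` with fields `name`,
#'   `sequence` and `seed`.
#' @export
mature_mirna <- function(name, sequence) {
  sequence <- rna_normalize(sequence, paste0("miRNA ", name))
  if (nchar(sequence) < 8L) stop2("mature miRNA must be at least 8 nt")
  structure(list(name = name, sequence = sequence,
                 seed = substr(sequence, 2L, 8L)),
            class = "MatureMiRNA")
}

#' @export
print.MatureMiRNA <- function(x, ...) {
  cat(sprintf("MatureMiRNA %s: %s (seed %s)\n", x$name, x$sequence, x$seed))
  invisible(x)
}

# Canonical site strings on the UTR sense strand (5'->3'):
#   core6     = reverse complement of miRNA nt 2-7
#   m8_char   = complement of miRNA nt 8 (immediately 5' of the core)
#   A1        = 'A' opposite miRNA nt 1 (immediately 3' of the core)
seed_patterns <- function(mir) {
  list(core6 = rna_revcomp(substr(mir$sequence, 2L, 7L)),
       m8_char = RNA_COMPLEMENT[[substr(mir$sequence, 8L, 8L)]])
}

#' Scan 3'UTR sequences for canonical microRNA seed sites
#'
#' Finds all canonical matches to the miRNA seed (nucleotides 2-8) in the
#' given UTR sequences and classifies each locus with its most specific
#' type: `8mer` (seed match at positions 2-8 plus an A opposite position
#' 1), `7mer-m8` (match at 2-8), `7mer-A1` (match at 2-7 plus the A), or
#' `6mer` (match at 2-7 only). DNA input is accepted (T is treated as U)
#' and matching is case-insensitive. Coordinates are 0-based, half-open,
#' on the UTR sense strand.
#'
#' @param utrs named character vector of UTR sequences (names are used as
#'   `utr_id`; unnamed input is indexed).
#' @param mir a [mature_mirna()].
#' @return data.frame with columns `utr_id`, `start`, `end`, `site_type`,
#'   `match`; zero rows when no site is found.
#' @export
scan_seed_sites <- function(utrs, mir) {
  if (!inherits(mir, "MatureMiRNA")) stop2("'mir' must be a mature_mirna()")
  if (is.null(names(utrs)))
    names(utrs) <- if (length(utrs) == 1L) "utr" else paste0("utr", seq_along(utrs))
  pat <- seed_patterns(mir)
  out <- lapply(names(utrs), function(id) {
    utr <- rna_normalize(utrs[[id]], paste0("UTR ", id))
    n <- nchar(utr)
    if (n < 6L) return(NULL)
    hits <- gregexpr(paste0("(?=", pat$core6, ")"), utr, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) return(NULL)
    res <- lapply(as.integer(hits), function(s) {
      has_m8 <- s > 1L && substr(utr, s - 1L, s - 1L) == pat$m8_char
      has_a1 <- s + 6L <= n && substr(utr, s + 6L, s + 6L) == "A"
      type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
              else if (has_a1) "7mer-A1" else "6mer"
      start0 <- (s - 1L) - has_m8
      end0 <- (s - 1L) + 6L + has_a1
      data.frame(utr_id = id, start = start0, end = end0, site_type = type,
                 match = substr(utr, start0 + 1L, end0))
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(utr_id = character(), start = integer(),
                      end = integer(), site_type = character(),
                      match = character())
  out
}

#' Read 3'UTR sequences from FASTA
#'
#' Record ids (first token of the header) are taken as gene symbols.
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Repression filter of the target screen
#'
#' Retains universe members that are down-regulated in the wild-type
#' activation contrast (`FC < max_fc` in WT-M1 vs WT-M0), the screen's
#' first filter. An optional significance filter on the same contrast can
#' be enabled with `alpha`.
#'
#' @param fc_wt [contrast()] result for WT-M1 vs WT-M0.
#' @param universe a [gene_set()] of candidate genes, e.g. from a seed-site
#'   scan or a precomputed prediction list.
#' @param max_fc fold-change ceiling; genes with `FC < max_fc` are kept.
#'   The default 1 keeps any down-regulated gene.
#' @param alpha optional p threshold (NULL disables the p filter).
#' @param p_value `"adjusted"` or `"raw"`, used when `alpha` is set.
#' @return a probe-matched [gene_set()]; empty (with a warning) when no
#'   universe member intersects the contrast or survives the filter.
#' @export
candidate_targets <- function(fc_wt, universe, max_fc = 1, alpha = NULL,
                              p_value = c("adjusted", "raw")) {
  p_value <- match.arg(p_value)
  if (!length(universe$members)) stop2("empty candidate universe")
  idx <- match_gene_set(fc_wt, universe, allow_missing = TRUE)
  if (!length(idx)) {
    warning("no universe gene found in the contrast; returning empty set",
            call. = FALSE)
    return(gene_set(character(), name = "candidate_targets", match = "probe"))
  }
  keep <- fc_wt$fc[idx] < max_fc
  if (!is.null(alpha)) {
    p <- if (p_value == "adjusted") fc_wt$p_adj else fc_wt$p_raw
    keep <- keep & p[idx] < alpha
  }
  if (!any(keep))
    warning("no candidate passed the repression filter", call. = FALSE)
  gene_set(fc_wt$probe_id[idx][keep], name = "candidate_targets",
           direction = "down", match = "probe")
}

#' Re-induction filter of the target screen
#'
#' Splits repressed candidates by their de-repression in the knockout under
#' activating stimulus: `reinduced` genes have `FC > 1` in the KO-M1 vs
#' WT-M1 contrast (expressed more without the microRNA), and `top` genes
#' reach at least `top_threshold`.
#'
#' @param candidates a [candidate_targets()] gene set.
#' @param fc_cross [contrast()] result for KO-M1 vs WT-M1.
#' @param top_threshold fold-change cut for the top set (inclusive).
#' @return list with `reinduced` and `top` gene sets and
#'   `fraction_reinduced`.
#' @export
reinduction_filter <- function(candidates, fc_cross, top_threshold = 2) {
  idx <- match_gene_set(fc_cross, candidates)
  fc <- fc_cross$fc[idx]
  list(reinduced = gene_set(fc_cross$probe_id[idx][fc > 1],
                            name = "reinduced", match = "probe"),
       top = gene_set(fc_cross$probe_id[idx][fc >= top_threshold],
                      name = "top_reinduced", match = "probe"),
       fraction_reinduced = if (length(fc)) mean(fc > 1) else NA_real_)
}

#' Pearson correlation of gene expression with a microRNA vector
#'
#' Correlates each gene's expression across samples with a per-sample
#' microRNA expression vector; the two-tailed p-value comes from
#' `t = R * sqrt(n-2) / sqrt(1-R^2)` with `n - 2` degrees of freedom.
#' Genes (or a microRNA vector) with zero variance give `R = NA` and are
#' flagged rather than dropped.
#'
#' @param em an ExpressionMatrix.
#' @param mir_vector numeric vector of microRNA expression, one value per
#'   matrix sample (aligned by name when named, by position otherwise).
#' @param genes optional [gene_set()] restricting the computation.
#' @return data.frame with `probe_id`, `gene_symbol`, `r`, `p`,
#'   `zero_variance`.
#' @export
correlate_with_mir <- function(em, mir_vector, genes = NULL) {
  ids <- colnames(em$E)
  if (!is.null(names(mir_vector))) {
    miss <- setdiff(ids, names(mir_vector))
    if (length(miss))
      stop2("miRNA vector missing sample(s): ", paste(miss, collapse = ", "))
    mir_vector <- mir_vector[ids]
  } else if (length(mir_vector) != length(ids)) {
    stop2("miRNA vector length must equal the number of samples")
  }
  n <- length(ids)
  if (n < 3L) stop2("need at least 3 samples for a correlation p-value")
  E <- em$E
  keep_genes <- em$genes
  if (!is.null(genes)) {
    cr_like <- data.frame(probe_id = em$genes$probe_id,
                          gene_symbol = em$genes$gene_symbol)
    idx <- match_gene_set(cr_like, genes)
    E <- E[idx, , drop = FALSE]
    keep_genes <- em$genes[idx, , drop = FALSE]
  }
  gene_var <- apply(E, 1L, stats::var)
  mir_flat <- stats::var(mir_vector) == 0
  r <- rep(NA_real_, nrow(E))
  ok <- gene_var > 0 & !mir_flat
  if (any(ok)) r[ok] <- as.numeric(stats::cor(t(E[ok, , drop = FALSE]), mir_vector))
  p <- rep(NA_real_, length(r))
  finite_r <- ok & abs(r) < 1
  tstat <- r[finite_r] * sqrt(n - 2) / sqrt(1 - r[finite_r]^2)
  p[finite_r] <- 2 * stats::pt(-abs(tstat), n - 2)
  p[ok & abs(r) == 1] <- 0
  data.frame(probe_id = keep_genes$probe_id,
             gene_symbol = keep_genes$gene_symbol,
             r = r, p = p, zero_variance = !ok, row.names = NULL)
}

#' Assemble the target-screen report
#'
#' One row per top re-induced candidate, sorted by ascending correlation R
#' (strongest inverse correlation first), with a significance flag at
#' `alpha` on the correlation p-value and the significant-row count
#' attached.
#'
#' @param rows data.frame with columns `gene`, `r`, `p_r`, `fc_wt`, `p_wt`
#'   (WT-M1 vs WT-M0), `fc_cross`, `p_cross` (KO-M1 vs WT-M1), `fc_ko`,
#'   `p_ko` (KO-M1 vs KO-M0).
#' @param alpha significance level for the correlation flag.
#' @return the rows sorted by `r`, with a `significant` column, class
#'   `"target_report"` and attribute `n_significant`.
#' @export
build_target_report <- function(rows, alpha = 0.05) {
  need <- c("gene", "r", "p_r", "fc_wt", "p_wt", "fc_cross", "p_cross",
            "fc_ko", "p_ko")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop2("report rows missing column(s): ", paste(miss, collapse = ", "))
  rows <- rows[order(rows$r), , drop = FALSE]
  rownames(rows) <- NULL
  rows$significant <- !is.na(rows$p_r) & rows$p_r < alpha
  structure(rows, class = c("target_report", "data.frame"),
            alpha = alpha, n_significant = sum(rows$significant))
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("target report: %d genes, %d significantly correlated at p < %g\n",
              nrow(x), attr(x, "n_significant"), attr(x, "alpha")))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Run the full candidate-target screen
#'
#' Chains the repression filter, the re-induction filter and the inverse
#' correlation screen, and assembles the report for the top re-induced
#' set. The chain is a pure filter: permuting gene order does not change
#' its output.
#'
#' @param em annotated ExpressionMatrix (all four groups).
#' @param mir_vector per-sample microRNA expression (see
#'   [correlate_with_mir()]).
#' @param universe candidate universe [gene_set()].
#' @param fc_wt,fc_ko,fc_cross the three screen contrasts (WT-M1 vs WT-M0,
#'   KO-M1 vs KO-M0, KO-M1 vs WT-M1).
#' @param max_fc repression-filter ceiling (see [candidate_targets()]).
#' @param top_threshold re-induction top cut.
#' @param alpha significance level for the correlation flag.
#' @return list with `candidates`, `reinduced`, `top`,
#'   `fraction_reinduced`, `correlations` and `report`.
#' @export
screen_targets <- function(em, mir_vector, universe, fc_wt, fc_ko, fc_cross,
                           max_fc = 1, top_threshold = 2, alpha = 0.05) {
  cand <- candidate_targets(fc_wt, universe, max_fc = max_fc)
  rein <- reinduction_filter(cand, fc_cross, top_threshold = top_threshold)
  cors <- correlate_with_mir(em, mir_vector,
                             genes = if (length(rein$top)) rein$top else NULL)
  top_probes <- rein$top$members
  iw <- match(top_probes, fc_wt$probe_id)
  ik <- match(top_probes, fc_ko$probe_id)
  ix <- match(top_probes, fc_cross$probe_id)
  ic <- match(top_probes, cors$probe_id)
  rows <- data.frame(gene = fc_wt$gene_symbol[iw],
                     r = cors$r[ic], p_r = cors$p[ic],
                     fc_wt = fc_wt$fc[iw], p_wt = fc_wt$p_adj[iw],
                     fc_cross = fc_cross$fc[ix], p_cross = fc_cross$p_adj[ix],
                     fc_ko = fc_ko$fc[ik], p_ko = fc_ko$p_adj[ik])
  if (!length(top_probes)) rows <- rows[0L, , drop = FALSE]
  list(candidates = cand, reinduced = rein$reinduced, top = rein$top,
       fraction_reinduced = rein$fraction_reinduced, correlations = cors,
       report = build_target_report(rows, alpha = alpha))
}
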