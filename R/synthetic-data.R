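#' Parameters for the synthetic expression generator
#'
#' Defines a two-genotype (WT/KO), two-condition (M0/M1) bulk expression
#' study with planted ground truth. Probes are assigned deterministically,
#' in index order, to classes before any noise is drawn, so truth counts
#' are exact:
#'
#' * `induced-dependent` / `induced-attenuated` - up in WT-M1 by a per-gene
#'   log2 effect `u`; in KO-M1 the effect is 0 (dependent) or `b * u`
#'   (attenuated, `b` = `attenuation_exponent`, so `FC_KO = FC_WT^b`).
#' * `repressed-dependent` / `repressed-attenuated` - the mirror image,
#'   down in WT-M1.
#' * `target` - direct microRNA targets: repressed in WT-M1 (where the
#'   microRNA is high) and fully restored in KO-M1, hence re-induced in
#'   the KO-M1 vs WT-M1 contrast and inversely correlated with the
#'   microRNA vector across samples.
#' * `null` - baseline plus noise only.
#'
#' Per-gene effect magnitudes are drawn uniformly from
#' `[effect_size, effect_size + effect_spread]` (log2 units), reflecting
#' the wide dynamic range of activation responses; `effect_spread = 0`
#' gives every planted gene exactly `effect_size`. Expression is
#' log2-scale: per-probe baseline `N(baseline_mean, baseline_sd)` plus the
#' group effect plus `N(0, noise_sd)` per measurement. The microRNA
#' expression vector is high in WT-M1 samples only.
#'
#' @param n_probes number of probes.
#' @param group_sizes named integer vector of samples per group; the
#'   default `c(WT_M0=3, WT_M1=3, KO_M0=3, KO_M1=2)` mirrors an unbalanced
#'   design where one KO sample failed quality control.
#' @param fraction_induced,fraction_repressed fractions of probes up- or
#'   down-regulated in WT-M1.
#' @param fraction_dependent fraction of induced (and of repressed) genes
#'   whose response is fully lost in the KO.
#' @param attenuation_exponent `b` applied to the non-dependent remainder.
#' @param n_targets number of planted direct-target probes (separate from
#'   the repressed classes).
#' @param effect_size minimum log2 effect of planted genes.
#' @param effect_spread width of the uniform log2-effect distribution.
#' @param target_repression log2 repression of target genes in WT-M1.
#' @param noise_sd per-measurement Gaussian noise SD (log2).
#' @param baseline_mean,baseline_sd per-probe baseline distribution (log2).
#' @param mir_baseline,mir_induction,mir_noise_sd microRNA vector: baseline
#'   level, added level in WT-M1 (7.5 log2 units is a ~180-fold
#'   induction), and noise SD.
#' @param seed mandatory RNG seed.
#' @return validated list of class `"generator_params"`.
#' @export
generator_params <- function(n_probes = 10000,
                             group_sizes = c(WT_M0 = 3, WT_M1 = 3,
                                             KO_M0 = 3, KO_M1 = 2),
                             fraction_induced = 0.05,
                             fraction_repressed = 0.05,
                             fraction_dependent = 0.5,
                             attenuation_exponent = 0.6,
                             n_targets = 30,
                             effect_size = 2,
                             effect_spread = 3,
                             target_repression = log2(3),
                             noise_sd = 0.25,
                             baseline_mean = 8, baseline_sd = 1.5,
                             mir_baseline = 4, mir_induction = 7.5,
                             mir_noise_sd = 0.25,
                             seed) {
  if (missing(seed)) stop2("'seed' is mandatory for reproducibility")
  for (f in c("fraction_induced", "fraction_repressed", "fraction_dependent"))
    assert_scalar_number(get(f), f, 0, 1)
  need <- c("WT_M0", "WT_M1", "KO_M0", "KO_M1")
  if (!all(need %in% names(group_sizes)))
    stop2("group_sizes needs entries ", paste(need, collapse = ", "))
  if (any(group_sizes < 2)) stop2("every group needs >= 2 samples")
  p <- list(n_probes = as.integer(n_probes),
            group_sizes = group_sizes[need],
            fraction_induced = fraction_induced,
            fraction_repressed = fraction_repressed,
            fraction_dependent = fraction_dependent,
            attenuation_exponent = attenuation_exponent,
            n_targets = as.integer(n_targets),
            effect_size = effect_size, effect_spread = effect_spread,
            target_repression = target_repression,
            noise_sd = noise_sd,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            mir_baseline = mir_baseline, mir_induction = mir_induction,
            mir_noise_sd = mir_noise_sd,
            seed = as.integer(seed))
  n_planted <- round(p$n_probes * (fraction_induced + fraction_repressed)) +
    p$n_targets
  if (n_planted > p$n_probes)
    stop2("planted classes exceed n_probes")
  structure(p, class = "generator_params")
}

synthetic_classes <- function(p) {
  n_ind <- round(p$n_probes * p$fraction_induced)
  n_rep <- round(p$n_probes * p$fraction_repressed)
  n_ind_dep <- round(n_ind * p$fraction_dependent)
  n_rep_dep <- round(n_rep * p$fraction_dependent)
  classes <- rep("null", p$n_probes)
  classes[seq_len(n_ind)] <-
    rep(c("induced-dependent", "induced-attenuated"),
        c(n_ind_dep, n_ind - n_ind_dep))
  classes[n_ind + seq_len(n_rep)] <-
    rep(c("repressed-dependent", "repressed-attenuated"),
        c(n_rep_dep, n_rep - n_rep_dep))
  classes[n_ind + n_rep + seq_len(p$n_targets)] <- "target"
  classes
}

#' Generate a synthetic expression study with planted truth
#'
#' See [generator_params()] for the planted structure. Output is
#' deterministic given the seed: the same parameters produce bit-identical
#' matrices.
#'
#' @param params a [generator_params()].
#' @return list with `matrix` (annotated [expression_matrix()]), `sheet`
#'   (the sample sheet) and `truth` (class `"synthetic_truth"`: per-probe
#'   `classes`, log2 `effect_wt`/`effect_ko`, `true_fc` data.frame with
#'   `fc_wt`, `fc_ko`, `fc_cross` [KO-M1 vs WT-M1], the per-sample
#'   `mir_vector`, and the `params`).
#' @export
generate_expression <- function(params) {
  p <- params
  set.seed(p$seed)
  classes <- synthetic_classes(p)
  n <- p$n_probes
  probe_ids <- sprintf("probe_%05d", seq_len(n))
  symbols <- sprintf("G%05d", seq_len(n))

  is_ind <- startsWith(classes, "induced")
  is_rep <- startsWith(classes, "repressed")
  is_tgt <- classes == "target"
  u <- numeric(n)
  u[is_ind] <- p$effect_size + p$effect_spread * stats::runif(sum(is_ind))
  u[is_rep] <- p$effect_size + p$effect_spread * stats::runif(sum(is_rep))

  effect_wt <- numeric(n)
  effect_wt[is_ind] <- u[is_ind]
  effect_wt[is_rep] <- -u[is_rep]
  effect_wt[is_tgt] <- -p$target_repression
  effect_ko <- numeric(n)
  att <- endsWith(classes, "attenuated")
  effect_ko[att] <- p$attenuation_exponent * effect_wt[att]

  sizes <- p$group_sizes
  groups <- rep(names(sizes), sizes)
  sample_ids <- unlist(lapply(names(sizes), function(g)
    paste(g, seq_len(sizes[[g]]), sep = "_")), use.names = FALSE)
  effect_by_group <- cbind(WT_M0 = 0, WT_M1 = effect_wt,
                           KO_M0 = 0, KO_M1 = effect_ko)

  baseline <- stats::rnorm(n, p$baseline_mean, p$baseline_sd)
  E <- baseline + effect_by_group[, groups, drop = FALSE] +
    matrix(stats::rnorm(n * length(groups), 0, p$noise_sd), n)
  dimnames(E) <- list(probe_ids, sample_ids)

  mir <- p$mir_baseline + p$mir_induction * (groups == "WT_M1") +
    stats::rnorm(length(groups), 0, p$mir_noise_sd)
  names(mir) <- sample_ids

  sheet <- data.frame(sample_id = sample_ids,
                      genotype = sub("_.*", "", groups),
                      condition = sub(".*_", "", groups))
  em <- join_sample_sheet(expression_matrix(E, symbols), sheet)
  truth <- structure(
    list(classes = classes,
         probe_ids = probe_ids, gene_symbols = symbols,
         effect_wt = effect_wt, effect_ko = effect_ko,
         true_fc = data.frame(probe_id = probe_ids,
                              fc_wt = 2^effect_wt, fc_ko = 2^effect_ko,
                              fc_cross = 2^(effect_ko - effect_wt)),
         mir_vector = mir, params = p),
    class = "synthetic_truth")
  list(matrix = em, sheet = sheet, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic truth:\n")
  print(table(x$classes))
  invisible(x)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# site string whose flanks pin down the requested canonical type
planted_site <- function(mir, site_type) {
  pat <- seed_patterns(mir)
  not_m8 <- setdiff(c("A", "C", "G", "U"), pat$m8_char)[1L]
  not_a <- "C"
  switch(site_type,
         "8mer" = paste0(pat$m8_char, pat$core6, "A"),
         "7mer-m8" = paste0(pat$m8_char, pat$core6, not_a),
         "7mer-A1" = paste0(not_m8, pat$core6, "A"),
         "6mer" = paste0(not_m8, pat$core6, not_a),
         stop2("unknown site type: ", site_type))
}

#' Generate 3'UTR sequences with planted seed sites
#'
#' Target-gene UTRs carry exactly one planted canonical site of the
#' requested type; background (non-target) UTRs are rejection-sampled to
#' contain no canonical site at all, giving the scanner a clean planted
#' truth.
#'
#' @param truth a `synthetic_truth` from [generate_expression()], or a
#'   character vector of target gene symbols.
#' @param mir a [mature_mirna()].
#' @param site_type planted site type.
#' @param n_background number of site-free non-target UTRs (ignored when
#'   `truth` is a plain character vector).
#' @param utr_length UTR length in nucleotides.
#' @param seed RNG seed; defaults to the truth's seed + 1.
#' @return named character vector of RNA sequences (names = gene symbols).
#' @export
generate_utrs <- function(truth, mir,
                          site_type = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                          n_background = 100, utr_length = 300, seed = NULL) {
  site_type <- match.arg(site_type)
  if (inherits(truth, "synthetic_truth")) {
    targets <- truth$gene_symbols[truth$classes == "target"]
    pool <- truth$gene_symbols[truth$classes != "target"]
    background <- utils::head(pool, n_background)
    seed <- seed %||% (truth$params$seed + 1L)
  } else {
    targets <- as.character(truth)
    background <- character()
    seed <- seed %||% 1L
  }
  if (!length(targets)) stop2("no target genes defined")
  set.seed(seed)
  site <- planted_site(mir, site_type)
  clean_utr <- function() {
    for (i in 1:1000) {
      s <- random_rna(utr_length)
      if (!nrow(scan_seed_sites(s, mir))) return(s)
    }
    stop2("could not sample a site-free UTR; increase utr_length variability")
  }
  plant <- function() {
    for (i in 1:1000) {
      s <- clean_utr()
      pos <- sample.int(utr_length - nchar(site) + 1L, 1L)
      s <- paste0(substr(s, 1L, pos - 1L), site,
                  substr(s, pos + nchar(site), utr_length))
      hits <- scan_seed_sites(s, mir)
      if (nrow(hits) == 1L && hits$site_type == site_type) return(s)
    }
    stop2("failed to plant a clean seed site")
  }
  utrs <- c(vapply(targets, function(g) plant(), ""),
            vapply(background, function(g) clean_utr(), ""))
  names(utrs) <- c(targets, background)
  utrs
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Generate a Ct table with planted relative quantities
#'
#' Emits reference-gene and target-gene Ct values per sample such that
#' comparative-Ct quantification against the calibrator group recovers the
#' planted relative quantities (exactly at zero noise, in expectation
#' otherwise).
#'
#' @param rq_by_group named vector of planted relative quantities, one per
#'   group; the calibrator group should have RQ 1.
#' @param target target gene name.
#' @param reference_gene reference gene name.
#' @param n_per_group replicates per group.
#' @param noise_sd per-well Gaussian Ct noise (cycles).
#' @param base_dct true dCt of the calibrator state (cycles).
#' @param ref_ct mean reference-gene Ct (cycles).
#' @param seed RNG seed.
#' @return a [ct_table()] with a `group` column.
#' @export
generate_ct_table <- function(rq_by_group, target = "Target",
                              reference_gene = "Hprt", n_per_group = 3,
                              noise_sd = 0, base_dct = 5, ref_ct = 20,
                              seed = 1) {
  if (is.null(names(rq_by_group)) || any(rq_by_group <= 0))
    stop2("'rq_by_group' must be a named vector of positive quantities")
  set.seed(seed)
  rows <- lapply(names(rq_by_group), function(g) {
    dct <- base_dct - log2(rq_by_group[[g]])
    do.call(rbind, lapply(seq_len(n_per_group), function(i) {
      id <- paste(g, i, sep = "_")
      ct_ref <- ref_ct + stats::rnorm(1, 0, noise_sd)
      ct_tgt <- ct_ref + dct + stats::rnorm(1, 0, noise_sd)
      data.frame(sample_id = id, gene = c(reference_gene, target),
                 ct = c(ct_ref, ct_tgt), group = g)
    }))
  })
  ct_table(do.call(rbind, rows), reference_gene)
}
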