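default_config <- function() {
  list(
    expression = NULL,       # TSV / series-matrix path; NULL => synthetic
    expression2 = NULL,      # optional second matrix, column-joined
    sample_sheet = NULL,
    targets_file = NULL,     # precomputed candidate-target list (symbols)
    utr_fasta = NULL,        # 3'UTR FASTA for the seed scan
    mirna_name = "miR-155-5p",
    mirna_sequence = "UUAAUGCUAAUUGUGAUAGGGGU",
    mir_probe = NULL,        # probe id carrying miRNA expression
    marker_panel_file = NULL,
    up_fc = 2, down_fc = 0.5, alpha = 0.05, top_threshold = 2,
    signature_p = "adjusted",
    candidate_max_fc = 1,
    cluster_metric = "correlation", cluster_linkage = "average",
    cluster_k = 2,
    generator = list(),      # generator_params() overrides for synthetic mode
    seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the documented defaults
#' (see [run_pipeline()]).
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop2(sprintf("stage '%s': %s", stage, conditionMessage(e))))
}

#' Run the full dependency-analysis pipeline
#'
#' Sequences the whole analysis: group contrasts, signature calling,
#' dependency partitioning with the power-law trend, the candidate-target
#' screen (seed-scan or list mode) and sample clustering, writing every
#' result plus a reproducibility manifest to `out_dir`. With no
#' `expression` input, a synthetic study is generated from
#' `config$generator` and `config$seed`, so the pipeline is runnable
#' end-to-end without external data. The run is deterministic given
#' (inputs, config, seed).
#'
#' @param config a config list (see [read_run_config()]) or path to a
#'   YAML file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all intermediate results (`contrasts`,
#'   `signature`, `partition`, `trend`, `affected`, `screen`,
#'   `dendrogram`, `summary`).
#' @export
run_pipeline <- function(config = list(), out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL

  data <- with_stage("load", {
    if (is.null(config$expression)) {
      gp <- do.call(generator_params,
                    utils::modifyList(config$generator,
                                      list(seed = config$seed)))
      gen <- generate_expression(gp)
      truth <- gen$truth
      list(em = gen$matrix, mir = gen$truth$mir_vector, mode = "synthetic")
    } else {
      em <- read_expression(config$expression)
      mode <- "single_matrix"
      if (!is.null(config$expression2)) {
        em2 <- read_expression(config$expression2)
        if (!identical(em$genes$probe_id, em2$genes$probe_id))
          stop2("the two matrices must share one probe universe")
        em <- expression_matrix(cbind(em$E, em2$E), em$genes$gene_symbol)
        mode <- "column_joined"
      }
      if (is.null(config$sample_sheet)) stop2("sample_sheet is required")
      em <- join_sample_sheet(em, read_sample_sheet(config$sample_sheet))
      mir <- if (!is.null(config$mir_probe)) {
        if (!config$mir_probe %in% em$genes$probe_id)
          stop2("mir_probe not in matrix: ", config$mir_probe)
        em$E[config$mir_probe, ]
      }
      list(em = em, mir = mir, mode = mode)
    }
  })
  em <- data$em

  contrasts <- with_stage("contrast", list(
    wt = contrast(em, "WT_M1", "WT_M0"),
    ko = contrast(em, "KO_M1", "KO_M0"),
    cross = contrast(em, "KO_M1", "WT_M1")))

  signature <- with_stage("signature",
    call_signature(contrasts$wt, up_fc = config$up_fc,
                   down_fc = config$down_fc, alpha = config$alpha,
                   p_value = config$signature_p))

  partition <- with_stage("dependency",
    classify_dependency(signature, contrasts$wt, contrasts$ko))
  trend <- with_stage("dependency",
    fit_fcfc_trend(contrasts$wt$fc, contrasts$ko$fc))
  affected <- with_stage("dependency",
    compile_affected_list(contrasts$wt, contrasts$ko, contrasts$cross,
                          up_fc = config$up_fc, down_fc = config$down_fc))

  mir <- mature_mirna(config$mirna_name, config$mirna_sequence)
  screen <- with_stage("target_screen", {
    universe <- if (!is.null(config$targets_file)) {
      read_gene_set(config$targets_file, name = "user_targets")
    } else if (!is.null(config$utr_fasta)) {
      hits <- scan_seed_sites(read_utr_fasta(config$utr_fasta), mir)
      gene_set(unique(hits$utr_id), name = "seed_scan_targets")
    } else if (data$mode == "synthetic") {
      utrs <- generate_utrs(truth, mir)
      hits <- scan_seed_sites(utrs, mir)
      gene_set(unique(hits$utr_id), name = "seed_scan_targets")
    }
    if (is.null(universe) || is.null(data$mir)) {
      message("target screen skipped (no candidate universe or miRNA vector)")
      NULL
    } else {
      screen_targets(em, data$mir, universe, contrasts$wt, contrasts$ko,
                     contrasts$cross, max_fc = config$candidate_max_fc,
                     top_threshold = config$top_threshold,
                     alpha = config$alpha)
    }
  })

  dend <- with_stage("clustering", {
    panel_probes <- unique(c(
      partition$probe_id[partition$direction == "up" &
                           partition$label == "dependent"],
      if (!is.null(screen)) screen$top$members))
    if (length(panel_probes) >= 2L) {
      cluster_samples(em,
                      gene_set(panel_probes, name = "cluster_panel",
                               match = "probe"),
                      metric = config$cluster_metric,
                      linkage = config$cluster_linkage)
    } else NULL
  })

  s <- attr(partition, "summary")
  summary <- list(
    n_up = signature$n_up, n_down = signature$n_down,
    pct_up_dependent = s$pct_up_dependent,
    pct_down_dependent = s$pct_down_dependent,
    pct_overall_dependent = s$pct_overall_dependent,
    trend = list(a = trend$a, b = trend$b, r_squared = trend$r_squared),
    n_affected = length(affected),
    fraction_reinduced = if (!is.null(screen)) screen$fraction_reinduced,
    n_top_targets = if (!is.null(screen)) length(screen$top),
    n_significant_targets = if (!is.null(screen))
      attr(screen$report, "n_significant"))

  with_stage("write", {
    out <- function(f) file.path(out_dir, f)
    for (nm in names(contrasts))
      write_contrast(contrasts[[nm]], out(paste0("contrast_", nm, ".tsv")))
    write_gene_set(signature$up, out("signature_up.txt"))
    write_gene_set(signature$down, out("signature_down.txt"))
    utils::write.table(as.data.frame(partition), out("dependency_partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_set(affected, out("affected_genes.txt"))
    if (!is.null(screen))
      utils::write.table(as.data.frame(screen$report), out("target_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dend)) {
      write_linkage(dend, out("sample_linkage.tsv"))
      write_newick(dend, out("sample_dendrogram.nwk"))
    }
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    manifest <- list(package = "mirdep",
                     version = as.character(utils::packageVersion("mirdep")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     input_mode = data$mode,
                     seed = config$seed,
                     config = config)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  })

  invisible(list(contrasts = contrasts, signature = signature,
                 partition = partition, trend = trend, affected = affected,
                 screen = screen, dendrogram = dend, truth = truth,
                 summary = summary, config = config))
}
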