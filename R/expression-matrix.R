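#' Construct an expression matrix
#'
#' Container for log2-scale expression values (probes x samples), probe-level
#' gene-symbol annotation and, after [join_sample_sheet()], per-sample
#' genotype/condition metadata. Analysis is probe-level throughout: gene
#' symbols are annotations and several probes may map to one gene; they are
#' never collapsed automatically.
#'
#' @param values numeric matrix of log2 expression intensities with unique
#'   probe identifiers as rownames and unique sample identifiers as colnames.
#' @param gene_symbols optional character vector of gene symbols, one per
#'   probe (many-to-one allowed). Defaults to the probe identifiers.
#' @return an object of class `"ExpressionMatrix"`: a list with elements
#'   `E` (the matrix), `genes` (data.frame `probe_id`, `gene_symbol`) and
#'   `samples` (NULL until a sample sheet is joined).
#' @export
expression_matrix <- function(values, gene_symbols = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop2("'values' must be a numeric matrix")
  probe_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop2("'values' must have probe rownames and sample colnames")
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop2("duplicate probe id(s): ", paste(dup, collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop2("duplicate sample id(s): ",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop2("expression values must all be finite")
  gene_symbols <- gene_symbols %||% probe_ids
  if (length(gene_symbols) != nrow(values))
    stop2("'gene_symbols' must have one entry per probe")
  structure(
    list(E = values,
         genes = data.frame(probe_id = probe_ids,
                            gene_symbol = as.character(gene_symbols)),
         samples = NULL),
    class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$E)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (log2 scale)\n",
              nrow(x$E), ncol(x$E)))
  if (!is.null(x$samples)) {
    tab <- table(group = paste(x$samples$genotype, x$samples$condition,
                               sep = "_"))
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  } else {
    cat("no sample sheet joined\n")
  }
  invisible(x)
}

series_matrix_marker <- "!series_matrix_table_begin"

#' Read an expression matrix from TSV or GEO series-matrix text
#'
#' Plain TSV layout: first column = probe id, optional second column
#' `gene_symbol` (any case), remaining columns = one sample each, values on
#' log2 scale. The GEO series-matrix dialect is detected by its
#' `!series_matrix_table_begin` marker line; all `!`-prefixed metadata lines
#' are ignored and the embedded ID_REF table is read.
#'
#' @param path path to the file.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(startsWith(lines, series_matrix_marker))) {
    begin <- which(startsWith(lines, series_matrix_marker))[1L]
    end <- which(startsWith(lines, "!series_matrix_table_end"))[1L]
    if (is.na(end) || end <= begin + 1L)
      stop2("malformed series-matrix file: missing or empty table block")
    lines <- lines[(begin + 1L):(end - 1L)]
    lines <- gsub("\"", "", lines)
  } else {
    lines <- lines[!startsWith(lines, "#")]
  }
  tab <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop2("expression table needs a probe column and at least one sample")
  probe_ids <- tab[[1L]]
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop2("duplicate probe id(s): ", paste(dup, collapse = ", "))
  tab2 <- tab[-1L]
  symbols <- NULL
  if (tolower(names(tab2)[1L]) %in% c("gene_symbol", "symbol", "gene")) {
    symbols <- tab2[[1L]]
    tab2 <- tab2[-1L]
  }
  values <- matrix(NA_real_, nrow(tab2), ncol(tab2),
                   dimnames = list(probe_ids, names(tab2)))
  for (j in seq_len(ncol(tab2))) {
    v <- suppressWarnings(as.numeric(tab2[[j]]))
    bad <- which(is.na(v) & !is.na(tab2[[j]]) & nzchar(tab2[[j]]))
    if (any(is.na(v))) {
      row <- if (length(bad)) bad[1L] else which(is.na(v))[1L]
      stop2(sprintf("non-numeric value '%s' at row %d (probe %s), column '%s'",
                    tab2[[j]][row], row, probe_ids[row], names(tab2)[j]))
    }
    values[, j] <- v
  }
  expression_matrix(values, symbols)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the plain TSV dialect; a
#' read-write-read round trip reproduces values exactly.
#' @param em an ExpressionMatrix.
#' @param path output path.
#' @export
write_expression <- function(em, path) {
  out <- data.frame(probe_id = em$genes$probe_id,
                    gene_symbol = em$genes$gene_symbol,
                    em$E, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Expected columns: `sample_id`, `genotype` (WT/KO), `condition` (M0/M1/M2)
#' and optionally `replicate`.
#' @param path path to the CSV file.
#' @return a data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "genotype", "condition")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop2("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  sheet$genotype <- toupper(sheet$genotype)
  sheet$condition <- toupper(sheet$condition)
  bad_g <- setdiff(unique(sheet$genotype), c("WT", "KO"))
  if (length(bad_g)) stop2("unknown genotype label(s): ", paste(bad_g, collapse = ", "))
  bad_c <- setdiff(unique(sheet$condition), c("M0", "M1", "M2"))
  if (length(bad_c)) stop2("unknown condition label(s): ", paste(bad_c, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop2("duplicate sample_id in sheet: ",
          paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  if (is.null(sheet$replicate)) {
    key <- paste(sheet$genotype, sheet$condition)
    sheet$replicate <- stats::ave(seq_along(key), key, FUN = seq_along)
  }
  sheet
}

#' Join a sample sheet onto an expression matrix
#'
#' Every matrix sample must appear exactly once in the sheet; extra sheet
#' rows are ignored with a warning. Unbalanced designs (e.g. 3/3/3/2 after a
#' failed-QC sample is dropped) are supported.
#'
#' @param em an ExpressionMatrix.
#' @param sheet a data.frame as from [read_sample_sheet()].
#' @return the ExpressionMatrix with `$samples` populated (rows in matrix
#'   column order).
#' @export
join_sample_sheet <- function(em, sheet) {
  sheet <- validate_sample_sheet(sheet)
  ids <- colnames(em$E)
  miss <- setdiff(ids, sheet$sample_id)
  if (length(miss))
    stop2("sample(s) missing from sheet: ", paste(miss, collapse = ", "))
  extra <- setdiff(sheet$sample_id, ids)
  if (length(extra))
    warning("ignoring sheet sample(s) not in matrix: ",
            paste(extra, collapse = ", "), call. = FALSE)
  em$samples <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  rownames(em$samples) <- NULL
  em
}

#' Group sizes of an annotated expression matrix
#'
#' @param em an ExpressionMatrix with a joined sample sheet.
#' @return named integer vector, names `GENOTYPE_CONDITION`.
#' @export
group_sizes <- function(em) {
  if (is.null(em$samples)) stop2("no sample sheet joined; see join_sample_sheet()")
  tab <- table(paste(em$samples$genotype, em$samples$condition, sep = "_"))
  stats::setNames(as.integer(tab), names(tab))
}

group_samples <- function(em, group) {
  g <- parse_group(group)
  which(em$samples$genotype == g[["genotype"]] &
          em$samples$condition == g[["condition"]])
}
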