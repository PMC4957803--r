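`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop2(sprintf("'%s' must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  invisible(x)
}

# geometric mean; RQ-type quantities are ratio scaled
gmean <- function(x) exp(mean(log(x)))

#' Parse a genotype x condition group label
#'
#' Accepts "WT_M1", "WT.M1", "WT:M1" or a length-2 character vector
#' c("WT", "M1").
#' @noRd
parse_group <- function(group) {
  if (length(group) == 1L) group <- strsplit(group, "[_.:]")[[1]]
  if (length(group) != 2L)
    stop2("group must be 'GENOTYPE_CONDITION' or c(genotype, condition), got: ",
          paste(group, collapse = " "))
  genotype <- toupper(group[[1]]); condition <- toupper(group[[2]])
  if (!genotype %in% c("WT", "KO"))
    stop2("unknown genotype '", group[[1]], "' (expected WT or KO)")
  if (!condition %in% c("M0", "M1", "M2"))
    stop2("unknown condition '", group[[2]], "' (expected M0, M1 or M2)")
  c(genotype = genotype, condition = condition)
}

group_label <- function(group) paste(parse_group(group), collapse = "_")
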