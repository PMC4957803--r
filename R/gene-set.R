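#' Construct a gene set
#'
#' A named, deduplicated, order-preserving collection of probe identifiers or
#' gene symbols, with a direction tag for signature sets. Symbol matching
#' throughout the package is case-insensitive (published gene lists mix
#' capitalisations of the same symbol).
#'
#' @param members character vector of probe ids or gene symbols.
#' @param name set name.
#' @param direction one of `"up"`, `"down"`, `"none"`.
#' @param match how members are matched against contrasts: `"probe"` or
#'   `"symbol"`.
#' @return an object of class `"GeneSet"`.
#' @export
gene_set <- function(members, name = "gene_set",
                     direction = c("none", "up", "down"),
                     match = c("symbol", "probe")) {
  direction <- match.arg(direction)
  match <- match.arg(match)
  members <- as.character(members)
  members <- members[nzchar(trimws(members))]
  members <- trimws(members)
  members <- members[!duplicated(tolower(members))]
  structure(list(name = name, members = members, direction = direction,
                 match = match),
            class = "GeneSet")
}

#' @export
length.GeneSet <- function(x) length(x$members)

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d members (%s-matched, direction %s)\n",
              x$name, length(x$members), x$match, x$direction))
  invisible(x)
}

#' Read a gene set from plain text, one entry per line
#'
#' Lines are trimmed and deduplicated case-insensitively, preserving first
#' occurrence order; blank lines and `#` comments are skipped.
#'
#' @param path path to the file.
#' @inheritParams gene_set
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, name = basename(path),
                          direction = c("none", "up", "down"),
                          match = c("symbol", "probe")) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop2("empty gene-set file: ", path)
  gene_set(lines, name = name, direction = match.arg(direction),
           match = match.arg(match))
}

#' Write a gene set as plain text
#' @param gs a GeneSet.
#' @param path output path.
#' @export
write_gene_set <- function(gs, path) {
  writeLines(gs$members, path)
  invisible(path)
}

# Rows of a contrast_result matching the members of a gene set.
# Symbol matching is case-insensitive; errors name any member absent from
# the contrast unless allow_missing.
match_gene_set <- function(cr, gs, allow_missing = FALSE) {
  key <- if (gs$match == "probe") cr$probe_id else tolower(cr$gene_symbol)
  members <- if (gs$match == "probe") gs$members else tolower(gs$members)
  idx <- match(members, key)
  if (anyNA(idx) && !allow_missing)
    stop2("gene set member(s) not found in contrast: ",
          paste(gs$members[is.na(idx)], collapse = ", "))
  idx[!is.na(idx)]
}
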