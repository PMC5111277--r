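#' Read a gene expression matrix from delimited text
#'
#' Expects genes in rows with identifiers in the first column and a header
#' row of sample ids. Empty cells and the literal strings `NA`/`"NaN"` become
#' missing values. Duplicate gene or sample ids, and non-numeric body cells,
#' are hard errors naming the offender.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter; default tab.
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per sample.
#' @seealso [write_expression()], [filter_genes()], [ddcor()]
#' @export
read_expression <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = c("", "NA", "NaN"), progress = FALSE)
  if (ncol(raw) < 2) abort("expression file needs a gene id column plus sample columns")
  genes <- raw[[1]]
  body <- raw[-1]
  parsed <- purrr::imap(body, function(col, nm) {
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value '", col[bad[1]], "' for gene '",
                   genes[bad[1]], "' in sample column '", nm, "'"))
    }
    num
  })
  out <- tibble::tibble(gene = genes, !!!parsed)
  check_expr_ids(out$gene, names(out)[-1])
  out
}

#' Write a gene expression matrix to delimited text
#'
#' Inverse of [read_expression()]: finite values round-trip bit-identically
#' (written at full precision), missing entries are written as empty cells.
#'
#' @param expr Expression tibble (gene column first) or matrix.
#' @param path Output path.
#' @param delim Field delimiter; default tab.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delim = "\t") {
  m <- as_expr_matrix(expr)
  readr::write_delim(expr_as_tibble(m), path, delim = delim, na = "")
  invisible(path)
}

#' Read a design matrix from delimited text
#'
#' First column holds sample ids; remaining columns are 0/1 condition
#' indicators with condition names in the header.
#'
#' @param path Path to a TSV file.
#' @param delim Field delimiter; default tab.
#' @return A tibble with a `sample` column and one 0/1 column per condition.
#' @export
read_design <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  names(raw)[1] <- "sample"
  as_design_matrix(raw) # validates
  raw
}

#' Build a design matrix from a vector of condition labels
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels Condition label per sample (character or factor), same
#'   length as `sample_ids`.
#' @return A design tibble: `sample` column plus one 0/1 indicator column
#'   per distinct label.
#' @examples
#' design_from_labels(paste0("s", 1:6), rep(c("A", "B"), each = 3))
#' @export
design_from_labels <- function(sample_ids, labels) {
  stopifnot(length(sample_ids) == length(labels))
  labels <- as.character(labels)
  conds <- unique(labels)
  ind <- purrr::map(conds, ~ as.numeric(labels == .x))
  tibble::tibble(sample = as.character(sample_ids), !!!setNames(ind, conds))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated as
#' set name, description, member genes. The description field is kept as an
#' optional category label (e.g. BP/CC/MF for GO-style collections).
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids, with a
#'   `category` attribute (named character vector, one entry per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short)) abort("GMT line(s) with fewer than 3 fields (name, description, genes)")
  sets <- purrr::map(fields, function(f) {
    g <- f[-(1:2)]
    unique(g[nzchar(g)])
  })
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (any(lengths(sets) == 0)) abort("GMT contains an empty gene set")
  attr(sets, "category") <- setNames(vapply(fields, `[[`, character(1), 2), names(sets))
  sets
}
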