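#' Read a log2 expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers (header `gene_id`), and numeric log2 expression values.
#' Duplicate gene or sample identifiers and non-numeric cells are hard
#' errors: downstream pairing and translation index by these identifiers.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids), in file order.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a gene_id column plus at least one sample", call. = FALSE)
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    stop("duplicate gene_id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, samples))
  bad <- which(is.na(vals) & !is.na(as.matrix(raw[-1L])), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric expression value at gene '", genes[bad[1, 1]],
         "', sample '", samples[bad[1, 2]], "'", call. = FALSE)
  if (any(!is.finite(vals)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]; round-trips values to full double
#' precision.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Columns: `sample_id`, `compound`, `organ` (liver/kidney), `dose`
#' (control/low/middle/high), `time_days`, `replicate_id`, `findings`
#' (semicolon-separated histopathology finding strings; empty = none).
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per sample; `findings` is a list-column of
#'   character vectors.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "compound", "organ", "dose", "time_days",
            "replicate_id", "findings")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta <- tibble::as_tibble(df[need])
  meta$time_days <- as.numeric(meta$time_days)
  meta$findings <- lapply(meta$findings, function(x) {
    x <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    x[nzchar(x)]
  })
  validate_metadata(meta)
}

#' Write a sample-metadata table
#' @param meta Metadata tibble as returned by [read_metadata()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  out$findings <- vapply(meta$findings, paste, "", collapse = ";")
  utils::write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a metadata tibble against the label schema
#'
#' Checks sample-id uniqueness and that organ/dose/time values are schema
#' levels; normalises `findings` to a list-column.
#'
#' @param meta Metadata tibble.
#' @param schema A [label_schema()].
#' @return The validated tibble (invisibly unchanged apart from
#'   `findings` normalisation).
#' @export
validate_metadata <- function(meta, schema = label_schema()) {
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  for (blk in c("organ", "dose")) {
    bad <- setdiff(unique(meta[[blk]]), schema$blocks[[blk]])
    if (length(bad))
      stop("unknown ", blk, " value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  bad_t <- setdiff(unique(meta$time_days), as.numeric(schema$blocks$time))
  if (length(bad_t))
    stop("unknown time_days value(s): ", paste(bad_t, collapse = ", "),
         call. = FALSE)
  if (!is.list(meta$findings))
    meta$findings <- lapply(meta$findings, function(x) x[nzchar(x)])
  meta
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Members are deduplicated (set semantics); an empty
#' set or a duplicated set name is an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[[`, "", 1L)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    stop("duplicate gene-set name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members[nzchar(members)]
  })
  empty <- nms[lengths(sets) == 0L]
  if (length(empty))
    stop("empty gene set(s): ", paste(empty, collapse = ", "), call. = FALSE)
  stats::setNames(sets, nms)
}
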