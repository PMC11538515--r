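#' Condition-label schema
#'
#' A condition label is the fixed-width binary vector handed to the
#' generators to state what a profile is (source label) and what the
#' translation should be (target label). It concatenates one-hot blocks for
#' organ, dose and exposure time, padded with reserved zero bits up to
#' `label_width`. The default width of 14 leaves a 4-bit reserved block
#' (2 organ + 4 dose + 4 time = 10 informative bits); the reserved bits are
#' always zero and exist so the width can carry additional covariates
#' without changing downstream layer shapes.
#'
#' @param organs,doses,times Level sets for the three one-hot blocks, in
#'   encoding order. Times are in days.
#' @param label_width Total label length; must be at least the summed block
#'   widths.
#' @return An object of class `label_schema`.
#' @examples
#' sc <- label_schema()
#' encode_label("liver", "low", 3, sc)
#' @export
label_schema <- function(organs = c("liver", "kidney"),
                         doses = c("control", "low", "middle", "high"),
                         times = c(3, 7, 14, 28),
                         label_width = 14L) {
  blocks <- list(organ = as.character(organs),
                 dose = as.character(doses),
                 time = as.character(times))
  used <- sum(lengths(blocks))
  if (label_width < used) {
    stop("label_width (", label_width, ") smaller than summed one-hot blocks (",
         used, ")", call. = FALSE)
  }
  structure(list(blocks = blocks, label_width = as.integer(label_width),
                 reserved = as.integer(label_width - used)),
            class = "label_schema")
}

#' @export
print.label_schema <- function(x, ...) {
  cat("<label_schema> width", x$label_width, "\n")
  for (nm in names(x$blocks))
    cat("  ", nm, ": ", paste(x$blocks[[nm]], collapse = ", "), "\n", sep = "")
  cat("  reserved zero bits:", x$reserved, "\n")
  invisible(x)
}

block_onehot <- function(value, levels, block) {
  value <- as.character(value)
  i <- match(value, levels)
  if (anyNA(i)) {
    stop("unknown ", block, " value(s): ",
         paste(unique(value[is.na(i)]), collapse = ", "),
         " (expected one of: ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  }
  out <- matrix(0L, length(value), length(levels))
  out[cbind(seq_along(value), i)] <- 1L
  out
}

#' Encode a treatment condition as a binary label vector
#'
#' Vectorised: passing n conditions returns an n x `label_width` matrix.
#'
#' @param organ,dose,time_days Condition fields; must be levels of the
#'   schema's blocks.
#' @param schema A [label_schema()].
#' @return An integer matrix (n x label_width); for a single condition a
#'   plain integer vector.
#' @seealso [decode_label()]
#' @export
encode_label <- function(organ, dose, time_days, schema = label_schema()) {
  stopifnot(inherits(schema, "label_schema"))
  n <- max(length(organ), length(dose), length(time_days))
  bits <- cbind(block_onehot(rep_len(organ, n), schema$blocks$organ, "organ"),
                block_onehot(rep_len(dose, n), schema$blocks$dose, "dose"),
                block_onehot(rep_len(time_days, n), schema$blocks$time, "time"))
  if (schema$reserved > 0) bits <- cbind(bits, matrix(0L, n, schema$reserved))
  if (n == 1L) as.integer(bits[1L, ]) else bits
}

#' Decode a binary label vector back to its condition fields
#'
#' @param bits Integer vector of length `label_width` (or matrix with such
#'   rows) as produced by [encode_label()].
#' @param schema A [label_schema()].
#' @return A tibble with columns `organ`, `dose`, `time_days`.
#' @export
decode_label <- function(bits, schema = label_schema()) {
  stopifnot(inherits(schema, "label_schema"))
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  if (ncol(bits) != schema$label_width)
    stop("label has width ", ncol(bits), ", schema expects ",
         schema$label_width, call. = FALSE)
  offset <- 0L
  out <- list()
  for (nm in names(schema$blocks)) {
    lv <- schema$blocks[[nm]]
    blk <- bits[, offset + seq_along(lv), drop = FALSE]
    if (any(rowSums(blk) != 1L))
      stop("block '", nm, "' is not one-hot", call. = FALSE)
    out[[nm]] <- lv[max.col(blk)]
    offset <- offset + length(lv)
  }
  if (schema$reserved > 0 &&
      any(bits[, offset + seq_len(schema$reserved), drop = FALSE] != 0L))
    stop("reserved label bits must be zero", call. = FALSE)
  tibble::tibble(organ = out$organ, dose = out$dose,
                 time_days = as.numeric(out$time))
}
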