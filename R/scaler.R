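#' Fit a per-gene min-max scaler on a training expression matrix
#'
#' The generators work on features scaled into \[0, 1\] and emit sigmoid
#' outputs; this scaler defines that mapping and its inverse back to log2
#' units. It is fitted on training data only (applied unchanged to test and
#' generated data) so the test set never leaks into the feature range.
#' Constant genes (min == max) transform to 0.5 and invert back to the
#' constant.
#'
#' @param train Numeric genes x samples matrix with gene rownames.
#' @param clip If `TRUE` (default), values outside the training range are
#'   clipped to \[0, 1\] on transform.
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(train, clip = TRUE) {
  stopifnot(is.matrix(train), nrow(train) > 0, ncol(train) > 0,
            !is.null(rownames(train)))
  structure(list(gene_ids = rownames(train),
                 min = apply(train, 1L, min),
                 max = apply(train, 1L, max),
                 clip = isTRUE(clip)),
            class = "feature_scaler")
}

check_scaler_genes <- function(scaler, mat) {
  if (is.null(rownames(mat)) || !identical(rownames(mat), scaler$gene_ids))
    stop("gene ids of matrix do not match the scaler's training genes",
         call. = FALSE)
}

#' Transform log2 expression into the scaler's \[0, 1\] feature space
#' @param scaler A [fit_scaler()] object.
#' @param mat Genes x samples matrix over the scaler's genes, same order.
#' @return Matrix of the same shape in \[0, 1\] (when `clip = TRUE`).
#' @export
apply_scaler <- function(scaler, mat) {
  stopifnot(inherits(scaler, "feature_scaler"))
  check_scaler_genes(scaler, mat)
  rng <- scaler$max - scaler$min
  const <- rng == 0
  rng[const] <- 1
  out <- (mat - scaler$min) / rng
  out[const, ] <- 0.5
  if (scaler$clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Map scaled features back to log2 expression units
#' @inheritParams apply_scaler
#' @param mat Genes x samples matrix of scaled values.
#' @export
invert_scaler <- function(scaler, mat) {
  stopifnot(inherits(scaler, "feature_scaler"))
  check_scaler_genes(scaler, mat)
  rng <- scaler$max - scaler$min
  out <- mat * rng + scaler$min
  out[rng == 0, ] <- scaler$min[rng == 0]
  out
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat("<feature_scaler>", length(x$gene_ids), "genes, clip =", x$clip, "\n")
  invisible(x)
}
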