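#' Split compounds into training and test sets
#'
#' Train/test separation is by compound, never by sample, so no compound's
#' profiles can appear on both sides (the leakage the design guards
#' against). Compounds lacking profiles in both organs are excluded with a
#' warning before splitting. At the full-cohort scale of 41 paired
#' compounds and `test_fraction = 0.22` this yields the 32/9 split used for
#' model development.
#'
#' @param metadata Sample metadata tibble (see [read_metadata()]).
#' @param test_fraction Fraction of paired compounds assigned to the test
#'   set (rounded to the nearest count, at least 1 per side).
#' @param seed Integer seed; the same seed always yields the same split.
#' @param test_compounds Optional explicit test-compound character vector,
#'   overriding the random draw (for reproducing a published membership).
#' @return A list with character vectors `train_compounds` and
#'   `test_compounds` (class `split_spec`).
#' @export
split_by_compound <- function(metadata, test_fraction = 0.2, seed = 1L,
                              test_compounds = NULL) {
  paired <- paired_compounds(metadata)
  if (length(paired) < 2L)
    stop("need at least 2 compounds with profiles in both organs", call. = FALSE)
  if (!is.null(test_compounds)) {
    bad <- setdiff(test_compounds, paired)
    if (length(bad))
      stop("test_compounds not in the paired set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    test <- sort(unique(test_compounds))
  } else {
    n_test <- max(1L, min(length(paired) - 1L,
                          round(test_fraction * length(paired))))
    test <- sort(with_seed(seed, sample(paired, n_test)))
  }
  structure(list(train_compounds = setdiff(paired, test),
                 test_compounds = test),
            class = "split_spec")
}

paired_compounds <- function(metadata) {
  tab <- dplyr::distinct(metadata, .data$compound, .data$organ) |>
    dplyr::count(.data$compound)
  dropped <- tab$compound[tab$n < 2L]
  if (length(dropped))
    warning("compound(s) lacking both organs excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  sort(tab$compound[tab$n == 2L])
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec>", length(x$train_compounds), "train /",
      length(x$test_compounds), "test compounds\n")
  invisible(x)
}

#' Build drug-specific cross-organ pairwise samples
#'
#' Each pair joins one source-organ profile with one target-organ profile of
#' the same compound and is emitted in both directions (`to_kidney`: liver
#' source, `to_liver`: kidney source). Under the default `"strict"` mode
#' every treated profile pairs with every treated profile of the other
#' organ, and controls pair only with controls of the same compound —
#' treated and control profiles never mix. `"all_within_compound"` lifts
#' the treated/control separation (all same-compound cross-organ pairs) for
#' sensitivity analysis. Pairing operates at the individual-rat level, so
#' pair counts scale with replicate numbers; at the full TG-GATEs scale
#' this construction yields 45,402 training pairs per generator.
#'
#' @param metadata Sample metadata tibble.
#' @param compounds Compounds to build pairs for (default: all compounds
#'   present in both organs).
#' @param pairing_mode `"strict"` (default) or `"all_within_compound"`.
#' @return Tibble with columns `source_sample_id`, `target_sample_id`,
#'   `direction`, `compound`, plus source/target condition fields.
#' @export
build_pairs <- function(metadata, compounds = NULL,
                        pairing_mode = c("strict", "all_within_compound")) {
  pairing_mode <- match.arg(pairing_mode)
  if (is.null(compounds))
    compounds <- suppressWarnings(paired_compounds(metadata))
  meta <- dplyr::filter(metadata, .data$compound %in% compounds)
  one_direction <- function(src_organ) {
    tgt_organ <- setdiff(c("liver", "kidney"), src_organ)
    direction <- paste0("to_", tgt_organ)
    purrr::map_dfr(compounds, function(cp) {
      src <- dplyr::filter(meta, .data$compound == cp, .data$organ == src_organ)
      tgt <- dplyr::filter(meta, .data$compound == cp, .data$organ == tgt_organ)
      if (nrow(src) == 0L || nrow(tgt) == 0L) {
        warning("compound '", cp, "' has no ", src_organ, "/", tgt_organ,
                " profiles; contributes no ", direction, " pairs",
                call. = FALSE)
        return(NULL)
      }
      grid <- tidyr::expand_grid(s = seq_len(nrow(src)), t = seq_len(nrow(tgt)))
      if (pairing_mode == "strict") {
        keep <- (src$dose[grid$s] == "control") == (tgt$dose[grid$t] == "control")
        grid <- grid[keep, , drop = FALSE]
      }
      tibble::tibble(
        source_sample_id = src$sample_id[grid$s],
        target_sample_id = tgt$sample_id[grid$t],
        direction = direction,
        compound = cp,
        source_organ = src_organ,
        source_dose = src$dose[grid$s],
        source_time = src$time_days[grid$s],
        target_organ = tgt_organ,
        target_dose = tgt$dose[grid$t],
        target_time = tgt$time_days[grid$t]
      )
    })
  }
  out <- dplyr::bind_rows(one_direction("liver"), one_direction("kidney"))
  if (nrow(out) == 0L)
    return(out)
  dplyr::arrange(out, .data$direction, .data$compound,
                 .data$source_sample_id, .data$target_sample_id)
}

#' Exhaustive pair-count oracle
#'
#' Slow, independent enumeration of how many pairs [build_pairs()] must
#' emit per direction: loops over every ordered cross-organ sample pair and
#' applies the pairing rules one pair at a time. Used to cross-check the
#' vectorised construction.
#'
#' @inheritParams build_pairs
#' @return Named numeric vector with counts for `to_liver` and `to_kidney`.
#' @export
pair_count_oracle <- function(metadata, compounds = NULL,
                              pairing_mode = c("strict", "all_within_compound")) {
  pairing_mode <- match.arg(pairing_mode)
  if (is.null(compounds))
    compounds <- suppressWarnings(paired_compounds(metadata))
  counts <- c(to_liver = 0, to_kidney = 0)
  for (i in seq_len(nrow(metadata))) {
    for (j in seq_len(nrow(metadata))) {
      a <- metadata[i, ]
      b <- metadata[j, ]
      if (a$organ == b$organ) next
      if (a$compound != b$compound) next
      if (!(a$compound %in% compounds)) next
      if (pairing_mode == "strict" &&
          (a$dose == "control") != (b$dose == "control")) next
      dir <- paste0("to_", b$organ)
      counts[dir] <- counts[dir] + 1
    }
  }
  counts
}
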