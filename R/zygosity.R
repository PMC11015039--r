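#' Aggregate CRISPR amplicon editing outcomes
#'
#' Merges allele rows with identical indel signatures by summing their
#' read support, converts counts to fractions, and ranks outcomes by
#' descending fraction. Ties are broken deterministically by signature
#' text order. The aggregation key is the indel signature (position plus
#' inserted/deleted sequence), not the full read sequence, so sequencing
#' errors elsewhere in the amplicon do not split a real allele.
#'
#' @param raw Tibble with a `signature` column and either `reads` (counts)
#'   or `fraction`; an optional logical `is_reference` is carried through.
#' @return Tibble of aggregated outcomes, ranked descending by `fraction`,
#'   with columns `signature`, `fraction`, `is_reference`.
#' @export
aggregate_outcomes <- function(raw) {
  if (is.null(raw) || nrow(raw) == 0L) {
    stop("empty editing-outcome table", call. = FALSE)
  }
  if (!"signature" %in% names(raw)) {
    stop("outcome table needs a 'signature' column", call. = FALSE)
  }
  if ("reads" %in% names(raw)) {
    raw$.w <- raw$reads
  } else if ("fraction" %in% names(raw)) {
    raw$.w <- raw$fraction
  } else {
    stop("outcome table needs a 'reads' or 'fraction' column",
         call. = FALSE)
  }
  if (!"is_reference" %in% names(raw)) raw$is_reference <- FALSE

  agg <- raw |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(fraction = sum(.data$.w),
                     is_reference = any(.data$is_reference),
                     .groups = "drop")
  total <- sum(agg$fraction)
  if (total <= 0) stop("zero total read support", call. = FALSE)
  agg$fraction <- agg$fraction / total
  dplyr::arrange(agg, dplyr::desc(.data$fraction), .data$signature)
}

#' Call clone zygosity from ranked editing outcomes
#'
#' A clone is called homozygous when the top editing outcome accounts for
#' strictly more than 85% of the two most frequent aggregated outcomes;
#' otherwise heterozygous. Reference (unedited) alleles are eligible for
#' either of the top-two slots, so an unedited clone is homozygous
#' reference. A clone with a single aggregated outcome is called
#' homozygous with `top_fraction_of_top_two = 1` and a low-complexity
#' warning.
#'
#' @param outcomes Ranked tibble from [aggregate_outcomes()].
#' @param hom_threshold Fraction of the top-two mass above which (strictly)
#'   the call is homozygous (default 0.85).
#' @return A one-row tibble: `call`, `top_fraction_of_top_two`,
#'   `top_signature`, `second_signature`, `top_is_reference`,
#'   `second_is_reference`.
#' @export
#' @examples
#' out <- aggregate_outcomes(tibble::tibble(
#'   signature = c("+1A", "-2del", "ref"),
#'   reads = c(90, 8, 2)))
#' call_zygosity(out)  # 0.90/(0.90+0.08) > 0.85 -> homozygous
call_zygosity <- function(outcomes, hom_threshold = 0.85) {
  if (nrow(outcomes) == 0L) {
    stop("no aggregated outcomes to call", call. = FALSE)
  }
  if (nrow(outcomes) == 1L) {
    warning("single aggregated outcome; calling homozygous with low ",
            "allele complexity", call. = FALSE)
    return(tibble::tibble(
      call = "homozygous", top_fraction_of_top_two = 1,
      top_signature = outcomes$signature[1],
      second_signature = NA_character_,
      top_is_reference = outcomes$is_reference[1],
      second_is_reference = NA
    ))
  }
  top2 <- outcomes$fraction[1] + outcomes$fraction[2]
  if (top2 <= 0) {
    stop("top two outcomes carry zero read mass", call. = FALSE)
  }
  ratio <- outcomes$fraction[1] / top2
  tibble::tibble(
    call = if (ratio > hom_threshold) "homozygous" else "heterozygous",
    top_fraction_of_top_two = ratio,
    top_signature = outcomes$signature[1],
    second_signature = outcomes$signature[2],
    top_is_reference = outcomes$is_reference[1],
    second_is_reference = outcomes$is_reference[2]
  )
}

#' Call zygosity for every clone in an allele table
#'
#' @param alleles Tibble with `clone_id` plus the columns
#'   [aggregate_outcomes()] expects.
#' @param hom_threshold Passed to [call_zygosity()].
#' @return One row per clone with the [call_zygosity()] fields.
#' @export
call_zygosity_table <- function(alleles, hom_threshold = 0.85) {
  stopifnot("clone_id" %in% names(alleles))
  alleles |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::group_modify(function(df, key) {
      call_zygosity(aggregate_outcomes(df), hom_threshold)
    }) |>
    dplyr::ungroup()
}
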