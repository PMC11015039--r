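#' Column-mapping dialect for GeneMapper-style peak exports
#'
#' Fragment-analysis software exports differ in their column headers. A
#' dialect maps the logical fields this package needs (`sample`, `size`,
#' `height`, and optionally `area` and `dye`) onto the column names found in
#' a given export. The default matches a GeneMapper 5 tab-delimited export.
#'
#' @param sample Column holding the sample identifier (often the sample
#'   file name).
#' @param size Column holding the fragment size estimate in bp.
#' @param height Column holding the peak height in relative fluorescence
#'   units (RFU).
#' @param area Column holding the peak area, or `NULL` if absent.
#' @param dye Column holding the dye/channel label, or `NULL` if absent.
#'
#' @return A named list of class `peak_dialect`.
#' @export
#' @examples
#' genemapper_dialect()
#' genemapper_dialect(sample = "Sample Name", size = "Size (bp)")
genemapper_dialect <- function(sample = "Sample File", size = "Size",
                               height = "Height", area = "Area",
                               dye = "Dye") {
  structure(
    list(sample = sample, size = size, height = height,
         area = area, dye = dye),
    class = "peak_dialect"
  )
}

#' Read a GeneMapper-style peak table
#'
#' Parses a tab-delimited table of sized fragment peaks into a tidy tibble
#' with one row per peak. Rows whose size or height fields are non-numeric
#' are rejected and reported (attribute `"rejected"`); rows whose size falls
#' outside a plausible range are kept but flagged (attribute
#' `"size_flagged"`), since unusually large fragments may be genuine
#' expansions. Within each sample, peaks are sorted ascending by size.
#'
#' @param path Path to a tab-delimited peak export.
#' @param dialect A [genemapper_dialect()] mapping logical fields to the
#'   file's column headers.
#' @param size_range Plausible fragment-size range in bp; peaks outside it
#'   are flagged, not dropped. Default 50--1200 bp spans the GeneScan 500
#'   LIZ regime through large expansions.
#' @param drop_dyes Optional character vector of dye labels to drop (e.g.
#'   the size-standard ladder channel, typically already consumed by the
#'   instrument software).
#'
#' @return A tibble of class `peak_tbl` with columns `sample_id`, `dye`,
#'   `size_bp`, `height`, `area`, sorted by sample then size. Attributes
#'   `rejected` (tibble of row numbers and reasons) and `size_flagged`
#'   (integer row indices) carry the parse report.
#' @export
read_peak_table <- function(path, dialect = genemapper_dialect(),
                            size_range = c(50, 1200), drop_dyes = NULL) {
  if (!file.exists(path)) {
    stop("peak table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character",
                           na.strings = c("", "NA"))
  if (nrow(raw) == 0L) {
    stop("empty peak table: ", path, call. = FALSE)
  }
  for (field in c("sample", "size", "height")) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("peak table is missing mandatory column '", col %||% field,
           "' (", field, ")", call. = FALSE)
    }
  }

  out <- tibble::tibble(
    sample_id = as.character(raw[[dialect$sample]]),
    dye = pick_optional(raw, dialect$dye, NA_character_),
    size_bp = suppressWarnings(as.numeric(raw[[dialect$size]])),
    height = suppressWarnings(as.numeric(raw[[dialect$height]])),
    area = suppressWarnings(as.numeric(pick_optional(raw, dialect$area,
                                                     NA_character_)))
  )

  bad_size <- is.na(out$size_bp) & !is.na(raw[[dialect$size]])
  bad_height <- is.na(out$height) & !is.na(raw[[dialect$height]])
  bad <- bad_size | bad_height | is.na(raw[[dialect$size]]) |
    is.na(raw[[dialect$height]])
  rejected <- tibble::tibble(
    row = which(bad),
    reason = ifelse(bad_size[bad] | is.na(raw[[dialect$size]])[bad],
                    "non-numeric size", "non-numeric height")
  )
  out <- out[!bad, , drop = FALSE]
  if (!is.null(drop_dyes)) {
    out <- out[!(out$dye %in% drop_dyes), , drop = FALSE]
  }
  out <- dplyr::arrange(out, .data$sample_id, .data$size_bp)
  flagged <- which(out$size_bp < size_range[1] | out$size_bp > size_range[2])

  structure(out,
            rejected = rejected,
            size_flagged = flagged,
            class = c("peak_tbl", class(out)))
}

pick_optional <- function(raw, col, default) {
  if (!is.null(col) && col %in% names(raw)) as.character(raw[[col]])
  else rep(default, nrow(raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a peak table in the default GeneMapper-style dialect
#'
#' Emits a tab-delimited file that [read_peak_table()] re-reads losslessly
#' (missing areas become empty fields and return as `NA`).
#'
#' @param table A peak tibble with at least `sample_id`, `size_bp`,
#'   `height`.
#' @param path Output path.
#' @param dialect Column-name mapping used for the header.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path, dialect = genemapper_dialect()) {
  if (nrow(table) == 0L) {
    stop("refusing to write an empty peak table", call. = FALSE)
  }
  out <- data.frame(
    a = table$sample_id,
    b = if ("dye" %in% names(table)) table$dye else NA_character_,
    c = table$size_bp,
    d = table$height,
    e = if ("area" %in% names(table)) table$area else NA_real_,
    check.names = FALSE
  )
  names(out) <- c(dialect$sample, dialect$dye %||% "Dye", dialect$size,
                  dialect$height, dialect$area %||% "Area")
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read an experiment sample sheet
#'
#' The sample sheet maps each sample to its run, clone, treatment and
#' timepoint, flags baseline (day-0) samples, and records the known repeat
#' length for calibration standards.
#'
#' @param path CSV with columns `sample_id`, `run_id`, `clone_id`,
#'   `treatment`, `timepoint_days`, `is_baseline`, `known_repeat`; extra
#'   columns (e.g. `replicate`) are carried through.
#' @return A tibble, validated as for [join_sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

validate_sample_sheet <- function(sheet) {
  needed <- c("sample_id", "run_id", "clone_id", "treatment",
              "timepoint_days", "is_baseline", "known_repeat")
  missing <- setdiff(needed, names(sheet))
  if (length(missing)) {
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- sheet$is_baseline & sheet$timepoint_days != 0
  if (any(bad, na.rm = TRUE)) {
    stop("baseline samples must have timepoint_days = 0: ",
         paste(sheet$sample_id[which(bad)], collapse = ", "),
         call. = FALSE)
  }
  invisible(sheet)
}

#' Join peaks with the sample sheet
#'
#' Annotates every peak row with its sample's run/clone/treatment/timepoint
#' metadata. Samples present in the peak table but absent from the sheet do
#' not block the join; they are listed in the reconciliation report
#' (attribute `"orphans"`) and their metadata is `NA`.
#'
#' @param table A peak tibble from [read_peak_table()].
#' @param sheet A sample sheet tibble keyed by `sample_id`.
#' @return The annotated peak tibble with attribute `orphans` (character
#'   vector of unmatched sample ids).
#' @export
join_sample_sheet <- function(table, sheet) {
  validate_sample_sheet(sheet)
  orphans <- setdiff(unique(table$sample_id), sheet$sample_id)
  if (length(orphans)) {
    warning(length(orphans), " sample(s) in peaks absent from sheet: ",
            paste(orphans, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(table, sheet, by = "sample_id")
  structure(joined, orphans = orphans,
            class = unique(c("peak_tbl", class(joined))))
}
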