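#' Generate a saturation-mutagenesis SNV set around splice junctions
#'
#' For each junction, covers the `flank` positions immediately upstream
#' and the `flank` positions immediately downstream of the exon-intron
#' boundary (the boundary falls between positions, so 2 * flank positions
#' per junction at defaults), truncated cleanly at the sequence ends.
#' Each covered position is mutated to the three alternative nucleotides;
#' positions covered by several junction windows are emitted once.
#'
#' @param sequence Reference nucleotide sequence (uppercase ACGT string,
#'   or anything coercible via `as.character`).
#' @param junctions Tibble with columns `seq_id`, `position` (1-based
#'   coordinate of the intron-side base adjacent to the boundary), `side`
#'   (`"donor"` or `"acceptor"`) and `strand` (`"+"` or `"-"`).
#' @param flank Flank width in nt on each side of the boundary
#'   (default 50).
#' @param seq_id Sequence identifier assigned to the SNVs (defaults to
#'   the junctions' `seq_id`).
#' @return Tibble of SNVs: `seq_id`, `position`, `ref`, `alt`, ordered by
#'   position then alt.
#' @export
generate_saturation_snvs <- function(sequence, junctions, flank = 50,
                                     seq_id = NULL) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  stopifnot(nrow(junctions) >= 1)
  if (any(junctions$position < 1 | junctions$position > n)) {
    stop("junction position outside sequence bounds", call. = FALSE)
  }
  # boundary between position-1 and position: window is the flank
  # positions on each side of that inter-base boundary
  covered <- sort(unique(unlist(lapply(junctions$position, function(p) {
    seq.int(max(1L, p - flank), min(n, p + flank - 1L))
  }))))
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(sequence, "")[[1]][covered]
  if (any(!ref %in% bases)) {
    stop("sequence contains non-ACGT characters in a mutagenesis window",
         call. = FALSE)
  }
  sid <- seq_id %||% (if ("seq_id" %in% names(junctions))
    junctions$seq_id[1] else "seq")
  out <- tibble::tibble(
    seq_id = sid,
    position = rep(covered, each = 3L),
    ref = rep(ref, each = 3L)
  )
  out$alt <- unlist(lapply(ref, function(r) setdiff(bases, r)))
  out
}

# Donor (5'ss) base frequencies, positions -3..+6 around the exon|intron
# boundary; obligate GT floored by a pseudocount at scoring time.
donor_pwm <- function() {
  m <- rbind(
    A = c(0.33, 0.60, 0.08, 0.00, 0.00, 0.49, 0.71, 0.06, 0.15),
    C = c(0.37, 0.13, 0.04, 0.00, 0.00, 0.03, 0.08, 0.05, 0.19),
    G = c(0.18, 0.14, 0.81, 1.00, 0.00, 0.45, 0.12, 0.84, 0.20),
    T = c(0.12, 0.13, 0.07, 0.00, 1.00, 0.03, 0.09, 0.05, 0.46)
  )
  colnames(m) <- as.character(c(-3:-1, 1:6))
  m
}

# Acceptor (3'ss): 12-nt polypyrimidine tract, spacer, obligate AG, and
# the first exonic base; positions -15..-1 | +1.
acceptor_pwm <- function() {
  py <- c(A = 0.10, C = 0.35, G = 0.10, T = 0.45)
  m <- cbind(
    matrix(rep(py, 12), nrow = 4,
           dimnames = list(names(py), NULL)),
    c(A = 0.25, C = 0.30, G = 0.20, T = 0.25),   # -3 spacer (N)
    c(A = 1.00, C = 0.00, G = 0.00, T = 0.00),   # -2 A
    c(A = 0.00, C = 0.00, G = 1.00, T = 0.00),   # -1 G
    c(A = 0.25, C = 0.15, G = 0.50, T = 0.10)    # +1 exon
  )
  colnames(m) <- as.character(c(-15:-1, 1))
  m
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Window around a junction in transcript orientation. `position` is the
# intron-side base adjacent to the boundary; donors read exon->intron,
# acceptors intron->exon. Returns NA if the window leaves the sequence.
junction_site_seq <- function(sequence, junction, n_exonic, n_intronic) {
  p <- junction$position
  n <- nchar(sequence)
  plus <- junction$strand != "-"
  if (junction$side == "donor") {
    if (plus) { lo <- p - n_exonic; hi <- p + n_intronic - 1L }
    else      { lo <- p - n_intronic + 1L; hi <- p + n_exonic }
  } else {
    if (plus) { lo <- p - n_intronic + 1L; hi <- p + n_exonic }
    else      { lo <- p - n_exonic; hi <- p + n_intronic - 1L }
  }
  if (lo < 1L || hi > n) return(NA_character_)
  win <- substr(sequence, lo, hi)
  if (plus) win else revcomp(win)
}

pwm_score <- function(site, pwm, pseudo = 1e-3) {
  bases <- strsplit(site, "")[[1]]
  if (length(bases) != ncol(pwm) || any(!bases %in% rownames(pwm))) {
    return(NA_real_)
  }
  f <- pmax(pwm[cbind(match(bases, rownames(pwm)), seq_along(bases))],
            pseudo)
  lo <- sum(log(f))
  best <- sum(log(pmax(apply(pwm, 2, max), pseudo)))
  worst <- sum(log(pmax(apply(pwm, 2, min), pseudo)))
  (lo - worst) / (best - worst)
}

#' Position-weight-matrix splice-site scorer
#'
#' A lightweight, fully deterministic splice scorer built from consensus
#' donor/acceptor base frequencies. It maps a site's summed log-frequency
#' onto [0, 1] (1 = exact consensus), so scores are probability-like and
#' the score interface matches heavyweight neural scorers: a backend is
#' any `function(sequence, junction) -> [0, 1]`. Intended for tests and
#' for exercising the screen without a neural network.
#'
#' @return A scorer function `(sequence, junction) -> numeric in [0, 1]`
#'   (`NA` if the site window leaves the sequence).
#' @export
pwm_splice_scorer <- function() {
  dpwm <- donor_pwm()
  apwm <- acceptor_pwm()
  function(sequence, junction) {
    sequence <- toupper(as.character(sequence))
    if (junction$side == "donor") {
      site <- junction_site_seq(sequence, junction, 3L, 6L)
      pwm_score(site, dpwm)
    } else {
      site <- junction_site_seq(sequence, junction, 1L, 15L)
      pwm_score(site, apwm)
    }
  }
}

#' Score saturation SNVs with a splice-scorer backend
#'
#' For each SNV, the relevant junctions are those whose flank window
#' covers its position; the delta is score(mutated) - score(reference)
#' for the junction where the change is largest in magnitude. Variants
#' are classified sensitizing (delta >= +threshold; predicted to enhance
#' pseudoexon inclusion), interfering (delta <= -threshold) or
#' nonsignificant. Scorer failures on individual variants are recorded
#' (`delta = NA`) and the batch continues.
#'
#' @param scorer A backend from e.g. [pwm_splice_scorer()].
#' @param snvs Tibble from [generate_saturation_snvs()], optionally with
#'   an `allele_frequency` column (MAF) used to classify variants as
#'   common (MAF > 1%), rare, or unknown.
#' @param sequence Reference sequence.
#' @param junctions Junction tibble (see [generate_saturation_snvs()]).
#' @param flank Flank width used to associate SNVs with junctions.
#' @param delta_threshold Significance cutoff on |delta| (default 0.1).
#' @return The SNV tibble with `delta`, `classification` and
#'   `frequency_class` columns, one row per input SNV, order preserved.
#' @export
score_variants <- function(scorer, snvs, sequence, junctions, flank = 50,
                           delta_threshold = 0.1) {
  sequence <- toupper(as.character(sequence))
  ref_scores <- vapply(seq_len(nrow(junctions)), function(j) {
    scorer(sequence, junctions[j, ])
  }, numeric(1))

  deltas <- vapply(seq_len(nrow(snvs)), function(i) {
    pos <- snvs$position[i]
    if (substr(sequence, pos, pos) != snvs$ref[i]) {
      stop("SNV ref allele at position ", pos,
           " does not match the sequence", call. = FALSE)
    }
    mutated <- sequence
    substr(mutated, pos, pos) <- snvs$alt[i]
    near <- which(pos >= junctions$position - flank &
                  pos <= junctions$position + flank - 1L)
    if (!length(near)) return(0)
    d <- vapply(near, function(j) {
      s <- tryCatch(scorer(mutated, junctions[j, ]),
                    error = function(e) NA_real_)
      s - ref_scores[j]
    }, numeric(1))
    if (all(is.na(d))) return(NA_real_)
    d[which.max(abs(d))]
  }, numeric(1))

  snvs$delta <- deltas
  snvs$classification <- dplyr::case_when(
    is.na(deltas) ~ NA_character_,
    deltas >= delta_threshold ~ "sensitizing",
    deltas <= -delta_threshold ~ "interfering",
    TRUE ~ "nonsignificant"
  )
  maf <- if ("allele_frequency" %in% names(snvs)) snvs$allele_frequency
         else rep(NA_real_, nrow(snvs))
  snvs$frequency_class <- dplyr::case_when(
    is.na(maf) ~ "unknown",
    maf > 0.01 ~ "common",
    TRUE ~ "rare"
  )
  snvs
}

#' Write scored SNVs as a minimal VCF 4.2 file
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns, with the splice
#' delta and classification in INFO when present.
#'
#' @param snvs SNV tibble (scored or not).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path) {
  info <- if ("delta" %in% names(snvs)) {
    sprintf("DELTA=%.6g;CLASS=%s", snvs$delta,
            snvs$classification %||% ".")
  } else rep(".", nrow(snvs))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=repeatgain",
    "##INFO=<ID=DELTA,Number=1,Type=Float,Description=\"Splice scorer delta (mut - ref)\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"sensitizing|interfering|nonsignificant\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  snvs$seq_id, snvs$position, snvs$ref, snvs$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Check whether an exon is annotated
#'
#' An exon is considered annotated when some exon record on the same
#' sequence in the annotation agrees with it at both boundaries within
#' the tolerance (1 bp by default). Coordinates are 1-based inclusive on
#' both ends, per GFF3 convention.
#'
#' @param exon A list or one-row data frame with `seq_id`, `start`,
#'   `end`.
#' @param annotation Path to a GFF3 file, or a `GRanges` of exon records
#'   (rows with other feature types are ignored either way).
#' @param tolerance Maximum boundary discrepancy in nt (default 1).
#' @return `"annotated"` or `"novel"`.
#' @export
check_exon_annotation <- function(exon, annotation, tolerance = 1) {
  if (is.character(annotation)) {
    annotation <- rtracklayer::import(annotation, format = "gff3")
  }
  if (!is.null(annotation$type)) {
    annotation <- annotation[annotation$type == "exon"]
  }
  same_seq <- as.character(GenomicRanges::seqnames(annotation)) ==
    as.character(exon$seq_id)
  hits <- same_seq &
    abs(GenomicRanges::start(annotation) - exon$start) <= tolerance &
    abs(GenomicRanges::end(annotation) - exon$end) <= tolerance
  if (any(hits)) "annotated" else "novel"
}

#' Row-normalized overlap matrix between named gene sets
#'
#' Entry (row, col) is |row intersect col| / |row|, so the diagonal is 1
#' and the matrix is not symmetric in general.
#'
#' @param gene_sets Named list (>= 2) of character vectors.
#' @return A numeric matrix with the set names on both dimensions.
#' @export
dataset_overlap <- function(gene_sets) {
  stopifnot(length(gene_sets) >= 2, !is.null(names(gene_sets)))
  gene_sets <- lapply(gene_sets, unique)
  sizes <- lengths(gene_sets)
  if (any(sizes == 0)) {
    stop("empty gene set(s): ",
         paste(names(gene_sets)[sizes == 0], collapse = ", "),
         call. = FALSE)
  }
  k <- length(gene_sets)
  m <- matrix(NA_real_, k, k,
              dimnames = list(names(gene_sets), names(gene_sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    m[i, j] <- length(intersect(gene_sets[[i]], gene_sets[[j]])) / sizes[i]
  }
  m
}

#' Read a newline-delimited gene set
#'
#' @param path Text file, one gene per line; blank lines ignored.
#' @return Character vector of gene identifiers.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
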