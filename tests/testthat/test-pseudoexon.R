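test_that("saturation windows have the enumerated sizes", {
  set.seed(10)
  s <- random_dna(400)
  jx <- function(pos) tibble::tibble(seq_id = "chr1", position = pos,
                                     side = "donor", strand = "+")
  expect_equal(nrow(generate_saturation_snvs(s, jx(200L))), 300L)
  two <- dplyr::bind_rows(jx(100L), jx(300L))  # disjoint windows
  expect_equal(nrow(generate_saturation_snvs(s, two)), 600L)
  expect_equal(nrow(generate_saturation_snvs(s, jx(31L))), 240L)
  expect_error(generate_saturation_snvs(s, jx(900L)), "bounds")
})

test_that("SNV counts match brute-force enumeration of covered bases", {
  set.seed(11)
  s <- random_dna(500)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    jx <- tibble::tibble(seq_id = "chr1",
                         position = sample(500, k),
                         side = sample(c("donor", "acceptor"), k, TRUE),
                         strand = sample(c("+", "-"), k, TRUE))
    covered <- logical(500)
    for (p in jx$position) {
      covered[max(1, p - 50):min(500, p + 49)] <- TRUE
    }
    snvs <- generate_saturation_snvs(s, jx)
    expect_equal(nrow(snvs), 3L * sum(covered))
    expect_equal(sort(unique(snvs$position)), which(covered))
    # each position mutated to exactly the 3 non-reference bases
    expect_true(all(snvs$ref != snvs$alt))
    expect_true(all(table(snvs$position) == 3L))
  }
})

test_that("the PWM scorer scores consensus sites at 1", {
  set.seed(12)
  scorer <- pwm_splice_scorer()
  s <- random_dna(300)
  substr(s, 147, 155) <- "CAGGTAAGT"  # consensus donor, boundary at 150
  jd <- tibble::tibble(seq_id = "x", position = 150L, side = "donor",
                       strand = "+")
  expect_equal(scorer(s, jd[1, ]), 1, tolerance = 1e-12)
  # minus-strand donor: reverse complement placed on the other side
  s2 <- random_dna(300)
  substr(s2, 145, 153) <- "ACTTACCTG"  # revcomp of CAGGTAAGT
  jm <- tibble::tibble(seq_id = "x", position = 150L, side = "donor",
                       strand = "-")
  expect_equal(scorer(s2, jm[1, ]), 1, tolerance = 1e-12)
})

test_that("restoring a consensus donor is classified sensitizing", {
  set.seed(13)
  s <- random_dna(300)
  substr(s, 147, 155) <- "CAGATAAGT"  # weak donor: obligate +1 G broken
  jd <- tibble::tibble(seq_id = "x", position = 150L, side = "donor",
                       strand = "+")
  snv <- tibble::tibble(seq_id = "x", position = 150L, ref = "A",
                        alt = "G")  # restores the exact consensus
  scored <- score_variants(pwm_splice_scorer(), snv, s, jd)
  expect_gt(scored$delta, 0)
  expect_equal(scored$classification, "sensitizing")
  # and breaking the obligate +2 T of a strong donor is interfering
  s2 <- s
  substr(s2, 147, 155) <- "CAGGTAAGT"
  snv2 <- tibble::tibble(seq_id = "x", position = 151L, ref = "T",
                         alt = "C")
  scored2 <- score_variants(pwm_splice_scorer(), snv2, s2, jd)
  expect_lt(scored2$delta, 0)
  expect_equal(scored2$classification, "interfering")
})

test_that("the reverse mutation negates the forward delta exactly", {
  set.seed(14)
  s <- random_dna(300)
  jd <- tibble::tibble(seq_id = "x", position = 150L, side = "donor",
                       strand = "+")
  snvs <- generate_saturation_snvs(s, jd, flank = 10)
  fwd <- score_variants(pwm_splice_scorer(), snvs, s, jd)
  for (i in which(fwd$delta != 0)) {
    mut <- s
    substr(mut, fwd$position[i], fwd$position[i]) <- fwd$alt[i]
    back <- fwd[i, c("seq_id", "position")]
    back$ref <- fwd$alt[i]
    back$alt <- fwd$ref[i]
    rev <- score_variants(pwm_splice_scorer(), back, mut, jd)
    expect_equal(rev$delta, -fwd$delta[i], tolerance = 1e-12)
  }
})

test_that("scoring is order-stable and one row per input SNV", {
  set.seed(15)
  s <- random_dna(400)
  jx <- tibble::tibble(seq_id = "x", position = c(120L, 260L),
                       side = c("acceptor", "donor"), strand = "+")
  snvs <- generate_saturation_snvs(s, jx)
  scored <- score_variants(pwm_splice_scorer(), snvs, s, jx)
  expect_equal(nrow(scored), nrow(snvs))
  expect_equal(scored$position, snvs$position)
  expect_equal(scored$alt, snvs$alt)
  expect_true(all(scored$delta >= -1 & scored$delta <= 1))
  expect_error(score_variants(pwm_splice_scorer(),
                              dplyr::mutate(snvs[1, ], ref = "N"),
                              s, jx),
               "does not match")
})

test_that("scored SNVs round-trip through the minimal VCF", {
  set.seed(16)
  s <- random_dna(300)
  jd <- tibble::tibble(seq_id = "chr7", position = 150L, side = "donor",
                       strand = "+")
  snvs <- generate_saturation_snvs(s, jd, flank = 5, seq_id = "chr7")
  scored <- score_variants(pwm_splice_scorer(), snvs, s, jd)
  path <- tempfile(fileext = ".vcf")
  write_snv_vcf(scored, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(scored))
  fields <- strsplit(body[1], "\t")[[1]]
  expect_equal(fields[1], "chr7")
  expect_match(fields[8], "DELTA=")
})

test_that("exon annotation check honors the 1 bp tolerance", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr2\ttest\tgene\t50\t400\t.\t+\t.\tID=gene1",
    "chr2\ttest\texon\t101\t200\t.\t+\t.\tID=exon1;Parent=gene1",
    "chr3\ttest\texon\t100\t200\t.\t+\t.\tID=exon2"
  ), gff)
  exon <- list(seq_id = "chr2", start = 100, end = 200)
  expect_equal(check_exon_annotation(exon, gff, tolerance = 1),
               "annotated")
  expect_equal(check_exon_annotation(exon, gff, tolerance = 0), "novel")
  far <- list(seq_id = "chr2", start = 103, end = 200)
  expect_equal(check_exon_annotation(far, gff, tolerance = 1), "novel")
  wrong_chr <- list(seq_id = "chr9", start = 100, end = 200)
  expect_equal(check_exon_annotation(wrong_chr, gff), "novel")
})

test_that("dataset overlap is row-normalized with unit diagonal", {
  sets <- list(A = paste0("g", 1:4), B = paste0("g", 1:2),
               C = c("x", "y"))
  m <- dataset_overlap(sets)
  expect_equal(m["A", "B"], 0.5)
  expect_equal(m["B", "A"], 1.0)
  expect_equal(m["A", "C"], 0)
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(dataset_overlap(list(A = "g1", B = character())),
               "empty")
})
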