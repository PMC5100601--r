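test_that("FASTA records are split into codons with the stop codon stripped", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">short desc text", "ATGCAGTAA",
               ">nine", paste0("ATG", strrep("GAA", 8), "TAA"),
               ">rna", "AUGGCUUGA"), f)
  cds <- read_cds_fasta(f)
  expect_equal(cds$orf_id, c("short", "nine", "rna"))
  expect_identical(cds$codons[[1]], c("ATG", "CAG"))
  expect_equal(cds$length, c(2L, 9L, 2L))
  expect_equal(cds$stop_codon, c("TAA", "TAA", "TGA"))
  # U and T equivalent at ingest, canonical alphabet is T
  expect_identical(cds$codons[[3]], c("ATG", "GCT"))
})

test_that("malformed FASTA records fail with per-record messages", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">bad_len", "ATGCA", ">ok", "ATGTAA"), f)
  expect_error(read_cds_fasta(f), "bad_len.*not a multiple of 3")
  writeLines(c(">ambig", "ATGNNNTAA"), f)
  expect_error(read_cds_fasta(f), "ambig.*ambiguity")
  writeLines(character(), f)
  expect_warning(out <- read_cds_fasta(f), "empty")
  expect_equal(nrow(out), 0)
})

test_that("write/read round-trips generated transcriptomes exactly", {
  tr <- make_trna_complement()
  tx <- make_transcriptome(
    50, tr,
    planted = tibble::tibble(focal_codon = "CAG", n = 10, count = 7,
                             placement = "dispersed"),
    seed = 21)
  f <- tempfile(fileext = ".fa")
  write_cds_fasta(tx$cds, f)
  back <- read_cds_fasta(f)
  expect_equal(back$orf_id, tx$cds$orf_id)
  expect_identical(back$codons, tx$cds$codons)
})

test_that("codon counts agree with an independent per-position tally", {
  tr <- make_trna_complement()
  tx <- make_transcriptome(
    20, tr,
    planted = tibble::tibble(focal_codon = "CAG", n = 8, count = 7,
                             placement = "dispersed"),
    seed = 33)
  counts <- codon_count(tx$cds, "CAG")$count
  brute <- vapply(tx$cds$codons, function(cv) length(which(cv == "CAG")), integer(1))
  expect_equal(counts, brute)
  expect_equal(counts[1:8], rep(7L, 8))
  expect_equal(counts[9:20], rep(0L, 12))
  # counts over all sense codons partition the length
  totals <- Reduce(`+`, lapply(codonqueue:::sense_codons(),
                               function(cd) codon_count(tx$cds, cd)$count))
  expect_equal(totals, tx$cds$length)
  expect_error(codon_count(tx$cds, "CAGG"), "triplet")
})

test_that("first codon position is the 5'-most occurrence or NA", {
  cds <- cds_table(c("a", "b"), list(c("ATG", "CAG", "CAG"), c("ATG", "GAA")))
  pos <- first_codon_position(cds, "CAG")$first_position
  expect_equal(pos, c(2L, NA_integer_))
  tr <- make_trna_complement()
  far <- far7_like_fixture(tr)
  fp <- first_codon_position(far, "CAG")$first_position
  expect_true(fp >= 2 && fp <= 24)
})

test_that("synonymous codon swapping moves every occurrence and conserves totals", {
  tr <- make_trna_complement()
  far <- far7_like_fixture(tr)
  caa0 <- codon_count(far, "CAA")$count
  swapped <- swap_codons(far, "CAG", "CAA")
  expect_equal(codon_count(swapped, "CAG")$count, 0L)
  expect_equal(codon_count(swapped, "CAA")$count, caa0 + 12L)
  expect_equal(swapped$length, far$length)
  # glutamine codon total conserved
  gln <- function(x) codon_count(x, "CAG")$count + codon_count(x, "CAA")$count
  expect_equal(gln(swapped), gln(far))
  # identity when from_codon is absent
  none <- manual_cds(rep("GAA", 10))
  expect_identical(swap_codons(none, "CAG", "CAA")$codons, none$codons)
  # reverse swap restores the original when to_codon was absent initially
  no_caa <- manual_cds(c(rep("GAA", 5), rep("CAG", 3)))
  expect_identical(swap_codons(swap_codons(no_caa, "CAG", "CAA"),
                               "CAA", "CAG")$codons,
                   no_caa$codons)
  expect_warning(swap_codons(no_caa, "CAG", "AAA"), "non-synonymous")
})

test_that("rare-codon ratio handles zero numerators, denominators and sentinels", {
  cds <- cds_table(
    c("two", "zero", "inf", "none"),
    list(c(rep("CAG", 10), rep("AGG", 5)),
         c(rep("AGG", 8)),
         c(rep("CAG", 4), "GAA"),
         c("GAA", "GAT")))
  rr <- rare_codon_ratio(cds, "CAG", c("CAG", "AGG", "CTC"))
  expect_equal(rr$ratio, c(2, 0, Inf, NaN))
  expect_error(rare_codon_ratio(cds, "CAG", character()), "nonempty")
  expect_error(rare_codon_ratio(cds, "CAG", c("AGG")), "belong")
})

test_that("per-ORF codon statistics match independent tallies on a transcriptome", {
  tr <- make_trna_complement()
  tx <- make_transcriptome(
    15, tr,
    planted = tibble::tibble(focal_codon = "CAG", n = 5, count = 6,
                             placement = "clustered_5prime"),
    seed = 4)
  st <- codon_stats(tx$cds, codons = c("CAG", "AGG"), rare_set = rare_codons(tr))
  brute_cag <- vapply(tx$cds$codons, function(cv) sum(cv == "CAG"), integer(1))
  brute_rare_other <- vapply(tx$cds$codons,
                             function(cv) sum(cv %in% setdiff(rare_codons(tr), "CAG")),
                             integer(1))
  expect_equal(st$n_CAG, brute_cag)
  expect_equal(st$rare_codon_ratio,
               ifelse(brute_rare_other > 0, brute_cag / brute_rare_other,
                      ifelse(brute_cag > 0, Inf, NaN)))
  expect_equal(st$length, tx$cds$length)
})
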