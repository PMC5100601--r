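#' Generate a synthetic tRNA complement
#'
#' Builds a tRNA table with a controlled contrast between single-gene-copy
#' species (GCN = 1, each the exclusive decoder of one rare codon) and
#' abundant multicopy species (GCN drawn from 5..11, partitioning the
#' background codons). The first single-copy species decodes CAG and the
#' background always contains its synonymous partner CAA (decoded by an
#' abundant species), so synonymous-swap experiments are supported out of
#' the box. With `n_single_copy + n_abundant = 42` the species partition all
#' 61 sense codons, mimicking a full cytoplasmic complement.
#'
#' @param n_single_copy number of single-copy (rare) species.
#' @param n_abundant number of abundant (GCN > 4) species.
#' @param seed integer seed; generation is reproducible.
#' @param codon_universe optional codon set to partition; defaults to a
#'   compact 9-codon background plus one rare codon per single-copy species,
#'   or to all 61 sense codons for a 42-species complement.
#' @return A [trna_table()] tibble.
#' @export
make_trna_complement <- function(n_single_copy = 3, n_abundant = 3, seed = 1,
                                 codon_universe = NULL) {
  if (n_single_copy + n_abundant < 1) abort("need at least one tRNA species")
  rare_pool <- c("CAG", "AGG", "CTC", "CGG", "CTA", "ACG", "TCG", "CCG",
                 "GGG", "TGT", "ATA", "CGC")
  if (is.null(codon_universe)) {
    if (n_single_copy + n_abundant >= 42) {
      codon_universe <- sense_codons()
    } else {
      if (n_single_copy > length(rare_pool))
        abort("too many single-copy species for the default rare-codon pool")
      background <- c("ATG", "GAA", "GAT", "GCT", "GCC", "CAA", "AAA", "AAG", "GGT")
      codon_universe <- c(rare_pool[seq_len(n_single_copy)], background)
    }
  }
  codon_universe <- assert_codon(codon_universe, "codon_universe")
  rare <- intersect(rare_pool, codon_universe)[seq_len(n_single_copy)]
  if (anyNA(rare)) abort("codon_universe lacks enough rare-pool codons")
  background <- setdiff(codon_universe, rare)
  if (length(background) < n_abundant)
    abort("codon_universe cannot cover the abundant species")
  # ATG first so the initiator-decoding species is always abundant
  background <- c(intersect("ATG", background), setdiff(background, "ATG"))
  groups <- split(background, rep(seq_len(n_abundant), length.out = length(background)))

  gc <- Biostrings::GENETIC_CODE
  revcomp <- function(cd) as.character(Biostrings::reverseComplement(Biostrings::DNAString(cd)))
  with_local_seed(seed, {
    gcn_ab <- sample(5:11, n_abundant, replace = TRUE)
    single <- tibble(
      name = sprintf("tRNA-%s-s%02d", gc[rare], seq_len(n_single_copy)),
      anticodon = vapply(rare, revcomp, character(1)),
      amino_acid = unname(gc[rare]),
      gene_copy_number = 1L,
      relative_abundance = 1,
      decoded_codons = as.list(rare)
    )
    first_cd <- vapply(groups, `[`, character(1), 1)
    abundant <- tibble(
      name = sprintf("tRNA-%s-a%02d", gc[first_cd], seq_len(n_abundant)),
      anticodon = vapply(first_cd, revcomp, character(1)),
      amino_acid = unname(gc[first_cd]),
      gene_copy_number = as.integer(gcn_ab),
      relative_abundance = as.numeric(gcn_ab),
      decoded_codons = unname(groups)
    )
    trna_table(dplyr::bind_rows(single, abundant))
  })
}

#' Generate a synthetic transcriptome with planted rare-codon motifs
#'
#' Emulates the structures the screens probe: a background of ORFs built
#' only from abundantly decoded codons (so they are exactly immune to
#' rare-tRNA depletion), plus planted ORFs carrying a chosen number of focal
#' rare codons at a controlled placement — `clustered_5prime` (within codons
#' 2..24, the queue-to-initiation geometry), `dispersed`, or
#' `clustered_3prime`. Every ORF starts with ATG; stop codons are appended
#' only on FASTA export.
#'
#' @param n_orfs total number of ORFs.
#' @param trna a [trna_table()]; defines the background (non-rare) codons
#'   and the rare set.
#' @param planted `NULL`, or a data frame with columns `focal_codon`,
#'   `n` (ORFs), `count` (codons per ORF), `placement`, and optionally
#'   `length`.
#' @param length_range inclusive range of ORF lengths in codons.
#' @param alpha_rule `"constant"` or `"log_uniform"`.
#' @param alpha constant initiation rate (1/s) for `"constant"`.
#' @param alpha_range range for `"log_uniform"`.
#' @param seed integer seed.
#' @return A list with `cds` (a [cds_table()]), `alpha` (tibble `orf_id`,
#'   `alpha`), and `truth` (per-ORF planted properties and the intended
#'   sensitivity label).
#' @export
make_transcriptome <- function(n_orfs, trna = make_trna_complement(),
                               planted = NULL, length_range = c(150, 350),
                               alpha_rule = c("constant", "log_uniform"),
                               alpha = 0.3, alpha_range = c(0.05, 0.5),
                               seed = 1) {
  alpha_rule <- match.arg(alpha_rule)
  rare <- rare_codons(trna)
  all_dec <- sort(unique(unlist(trna$decoded_codons)))
  background <- setdiff(all_dec, c(rare, "ATG", stop_codons()))
  if (length(background) == 0) abort("complement leaves no background codons")
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    planted$focal_codon <- assert_codon(planted$focal_codon, "focal_codon")
    bad <- setdiff(planted$placement,
                   c("clustered_5prime", "dispersed", "clustered_3prime"))
    if (length(bad) > 0)
      abort(sprintf("unknown placement(s): %s", paste(bad, collapse = ", ")))
    if (sum(planted$n) > n_orfs) abort("more planted ORFs than n_orfs")
  }

  # sample() semantics change for length-1 pools; always index the pool
  draw <- function(pool, n, replace = FALSE)
    pool[sample.int(length(pool), n, replace = replace)]

  with_local_seed(seed, {
    lens <- draw(length_range[1]:length_range[2], n_orfs, replace = TRUE)
    focal <- rep(NA_character_, n_orfs)
    count <- rep(0L, n_orfs)
    placement <- rep(NA_character_, n_orfs)
    next_orf <- 1L
    plant_rows <- list()
    if (!is.null(planted)) {
      for (r in seq_len(nrow(planted))) {
        if (planted$n[r] < 1) next
        ids <- next_orf:(next_orf + planted$n[r] - 1L)
        next_orf <- next_orf + planted$n[r]
        focal[ids] <- planted$focal_codon[r]
        count[ids] <- planted$count[r]
        placement[ids] <- planted$placement[r]
        if (!is.null(planted[["length"]]) && !is.na(planted$length[r]))
          lens[ids] <- planted$length[r]
      }
    }
    codons <- vector("list", n_orfs)
    firstpos <- rep(NA_integer_, n_orfs)
    for (i in seq_len(n_orfs)) {
      L <- lens[i]
      cv <- c("ATG", draw(background, L - 1, replace = TRUE))
      if (count[i] > 0) {
        # clustered_5prime sits in the 5' region but downstream of the
        # 9-codon initiation clearance window, so depletion acts through
        # ribosome queueing (which dissipates at low initiation rate)
        # rather than through direct occlusion of codons 1..9 by a single
        # slow ribosome (which would not)
        pos_pool <- switch(placement[i],
          clustered_5prime = 10:min(24L, L),
          dispersed = 2:L,
          clustered_3prime = max(2L, L - 22L):L)
        if (count[i] > length(pos_pool))
          abort(sprintf("cannot plant %d codons in a window of %d positions",
                        count[i], length(pos_pool)))
        pp <- sort(draw(pos_pool, count[i]))
        cv[pp] <- focal[i]
        firstpos[i] <- pp[1]
      }
      codons[[i]] <- cv
    }
    orf_ids <- sprintf("ORF%04d", seq_len(n_orfs))
    alphas <- switch(alpha_rule,
      constant = rep(alpha, n_orfs),
      log_uniform = exp(stats::runif(n_orfs, log(alpha_range[1]), log(alpha_range[2]))))
    cds <- cds_table(orf_ids, codons)
    truth <- tibble(
      orf_id = orf_ids, length = lens, focal_codon = focal,
      planted_count = count, first_position = firstpos,
      placement = placement, alpha = alphas,
      sensitive_expected = !is.na(placement) &
        placement == "clustered_5prime" & focal %in% rare)
    list(cds = cds, alpha = tibble(orf_id = orf_ids, alpha = alphas),
         truth = truth)
  })
}

#' A FAR7-like queue-prone fixture
#'
#' One synthetic 221-codon ORF carrying 12 CAG codons clustered within
#' codons 2..24 — the composition of a short ORF whose translation is
#' elongation-limited under CAG-decoder depletion at physiological
#' initiation rates. Purely synthetic: the background codons come from the
#' complement's abundant species, not from any genomic sequence.
#'
#' @param trna a [trna_table()] whose rare set contains CAG.
#' @param seed integer seed.
#' @param length ORF length in codons.
#' @param n_focal number of planted CAG codons.
#' @return A single-row [cds_table()].
#' @export
far7_like_fixture <- function(trna = make_trna_complement(), seed = 1,
                              length = 221, n_focal = 12) {
  tx <- make_transcriptome(
    1, trna,
    planted = tibble(focal_codon = "CAG", n = 1, count = n_focal,
                     placement = "clustered_5prime", length = length),
    seed = seed)
  cds <- tx$cds
  cds$orf_id <- "FAR7like"
  cds
}
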