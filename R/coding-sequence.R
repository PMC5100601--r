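#' Coding-sequence tables
#'
#' A transcriptome is represented as a tibble with one row per open reading
#' frame (ORF): `orf_id` (character, unique), `codons` (list-column of
#' character vectors, one sense codon per lattice site), `length` (codons),
#' and `stop_codon` (the trailing stop stripped at ingest, or `NA`). Stop
#' codons are never part of the lattice; termination is modelled as exit from
#' the last sense codon.
#'
#' @param orf_id character vector of ORF identifiers.
#' @param codons list of character vectors of sense codons (1-based positions).
#' @param stop_codon optional character vector of stripped stop codons.
#' @return A `cds_tbl` tibble.
#' @examples
#' cds_table("orf1", list(c("ATG", "CAG", "GAA")))
#' @export
cds_table <- function(orf_id, codons, stop_codon = NA_character_) {
  if (!is.list(codons)) codons <- list(codons)
  codons <- lapply(codons, function(cv) {
    cv <- canonical_codon(cv)
    bad <- cv[!is_valid_codon(cv)]
    if (length(bad) > 0)
      abort(sprintf("invalid codon(s): %s", paste(unique(bad), collapse = ", ")))
    if (length(cv) > 0 && cv[length(cv)] %in% stop_codons())
      abort("trailing stop codon must be stripped before building a cds_tbl")
    cv
  })
  if (anyDuplicated(orf_id)) abort("duplicate orf_id in coding-sequence table")
  out <- tibble(
    orf_id = as.character(orf_id),
    codons = codons,
    length = vapply(codons, length, integer(1)),
    stop_codon = rep_len(stop_codon, length(codons))
  )
  if (any(out$length < 1)) abort("every coding sequence needs at least one codon")
  class(out) <- c("cds_tbl", class(out))
  out
}

#' Read coding sequences from a nucleotide FASTA file
#'
#' Each record is split into codon triplets. A trailing stop codon (TAA, TAG
#' or TGA) is stripped from the lattice and kept in the `stop_codon` column.
#' `U` and `T` are treated as equivalent; the internal alphabet is DNA.
#'
#' @param path path to a (possibly RNA) FASTA file of coding sequences.
#' @return A [cds_table()] tibble with one row per record.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    warn(sprintf("empty FASTA file: %s", path))
    return(cds_table(character(), list())[0, ])
  }
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- canonical_codon(as.character(seqs))
  problems <- character()
  codons <- vector("list", length(chars))
  stops <- rep(NA_character_, length(chars))
  for (i in seq_along(chars)) {
    s <- chars[[i]]
    if (nchar(s) %% 3 != 0) {
      problems <- c(problems, sprintf("%s: length %d is not a multiple of 3", ids[i], nchar(s)))
      next
    }
    if (grepl("[^ACGT]", s)) {
      problems <- c(problems, sprintf("%s: ambiguity or non-nucleotide characters", ids[i]))
      next
    }
    cv <- substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
    if (length(cv) > 0 && cv[length(cv)] %in% stop_codons()) {
      stops[i] <- cv[length(cv)]
      cv <- cv[-length(cv)]
    }
    if (length(cv) == 0) {
      problems <- c(problems, sprintf("%s: no sense codons after stop stripping", ids[i]))
      next
    }
    if (any(cv %in% stop_codons()))
      warn(sprintf("%s: internal stop codon kept as a lattice site", ids[i]))
    codons[[i]] <- cv
  }
  if (length(problems) > 0)
    abort(c("invalid coding-sequence record(s):", problems))
  cds_table(ids, codons, stops)
}

#' Write a coding-sequence table to FASTA
#'
#' The stripped stop codon (default `TAA` where unknown) is re-appended so
#' that [read_cds_fasta()] round-trips the table exactly.
#'
#' @param cds a [cds_table()] tibble.
#' @param path output path.
#' @param default_stop stop codon used where `stop_codon` is `NA`.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path, default_stop = "TAA") {
  stops <- ifelse(is.na(cds$stop_codon), default_stop, cds$stop_codon)
  seqs <- vapply(seq_len(nrow(cds)),
                 function(i) paste0(paste(cds$codons[[i]], collapse = ""), stops[i]),
                 character(1))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, cds$orf_id)), path, width = 60L)
  invisible(path)
}

#' Count occurrences of a codon in each coding sequence
#'
#' @param cds a [cds_table()] tibble.
#' @param codon a nucleotide triplet.
#' @return A tibble with `orf_id`, `codon`, `count`.
#' @export
codon_count <- function(cds, codon) {
  codon <- assert_codon(codon)
  counts <- vapply(cds$codons, function(cv) sum(cv == codon), integer(1))
  tibble(orf_id = cds$orf_id, codon = codon, count = counts)
}

#' 1-based position of the first (5'-most) occurrence of a codon
#'
#' @inheritParams codon_count
#' @return A tibble with `orf_id`, `codon`, `first_position` (`NA` if absent).
#' @export
first_codon_position <- function(cds, codon) {
  codon <- assert_codon(codon)
  pos <- vapply(cds$codons, function(cv) {
    i <- which(cv == codon)
    if (length(i) == 0) NA_integer_ else i[1]
  }, integer(1))
  tibble(orf_id = cds$orf_id, codon = codon, first_position = pos)
}

#' Replace every occurrence of one codon by another
#'
#' Used for in silico synonymous recoding (e.g. CAG -> CAA). Warns, but does
#' not fail, when the two codons encode different amino acids.
#'
#' @inheritParams codon_count
#' @param from_codon,to_codon nucleotide triplets.
#' @return A [cds_table()] with the substitution applied; lengths unchanged.
#' @export
swap_codons <- function(cds, from_codon, to_codon) {
  from_codon <- assert_codon(from_codon, "from_codon")
  to_codon <- assert_codon(to_codon, "to_codon")
  gc <- Biostrings::GENETIC_CODE
  if (!identical(unname(gc[from_codon]), unname(gc[to_codon])))
    warn(sprintf("non-synonymous swap: %s (%s) -> %s (%s)",
                 from_codon, gc[from_codon], to_codon, gc[to_codon]))
  out <- cds
  out$codons <- lapply(cds$codons, function(cv) {
    cv[cv == from_codon] <- to_codon
    cv
  })
  out
}

#' Focal rare-codon content normalised to other rare codons
#'
#' For each ORF, the count of `focal_codon` divided by the summed count of
#' the remaining codons in `rare_set`. The ratio is `Inf` when only the focal
#' codon occurs and `NaN` (undefined) when neither does.
#'
#' @inheritParams codon_count
#' @param focal_codon the focal rare codon; must belong to `rare_set`.
#' @param rare_set character vector of rare codons (by default, codons decoded
#'   exclusively by single-gene-copy tRNAs; see [rare_codons()]).
#' @return A tibble with `orf_id`, `focal_count`, `other_rare_count`, `ratio`.
#' @export
rare_codon_ratio <- function(cds, focal_codon, rare_set) {
  focal_codon <- assert_codon(focal_codon, "focal_codon")
  if (length(rare_set) == 0) abort("`rare_set` must be nonempty")
  rare_set <- assert_codon(rare_set, "rare_set")
  if (!focal_codon %in% rare_set) abort("`focal_codon` must belong to `rare_set`")
  others <- setdiff(rare_set, focal_codon)
  foc <- vapply(cds$codons, function(cv) sum(cv == focal_codon), integer(1))
  oth <- vapply(cds$codons, function(cv) sum(cv %in% others), integer(1))
  tibble(
    orf_id = cds$orf_id,
    focal_count = foc,
    other_rare_count = oth,
    ratio = ifelse(oth > 0, foc / oth, ifelse(foc > 0, Inf, NaN))
  )
}

#' Per-ORF codon composition statistics
#'
#' One-stop summary used by the screening workflow: length, per-codon counts,
#' first focal position, and the rare-codon ratio when a rare set is given.
#'
#' @inheritParams codon_count
#' @param codons triplets to count (first one is the focal codon).
#' @param rare_set optional rare-codon set for [rare_codon_ratio()].
#' @return A tibble with one row per ORF.
#' @export
codon_stats <- function(cds, codons = "CAG", rare_set = NULL) {
  codons <- assert_codon(codons)
  out <- tibble(orf_id = cds$orf_id, length = cds$length)
  for (cd in codons)
    out[[paste0("n_", cd)]] <- codon_count(cds, cd)$count
  out$first_position <- first_codon_position(cds, codons[1])$first_position
  if (!is.null(rare_set)) {
    rr <- rare_codon_ratio(cds, codons[1], rare_set)
    out$rare_codon_ratio <- rr$ratio
  }
  out
}
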