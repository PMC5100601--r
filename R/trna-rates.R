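#' tRNA complement tables
#'
#' A tRNA complement is a tibble with one row per cytoplasmic tRNA species:
#' `name` (unique), `anticodon`, `amino_acid` (1-letter), `gene_copy_number`
#' (integer >= 1), `relative_abundance` (defaults to the gene copy number,
#' the genomic proxy for cellular tRNA concentration), and `decoded_codons`
#' (list-column of triplets; the codon -> tRNA assignment is data, not code).
#'
#' @param df a data frame with the columns above (`decoded_codons` may be a
#'   comma-separated string column).
#' @return A validated `trna_tbl` tibble.
#' @export
trna_table <- function(df) {
  df <- as_tibble(df)
  need <- c("name", "anticodon", "amino_acid", "gene_copy_number", "decoded_codons")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    abort(sprintf("tRNA table is missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$name))
    abort(sprintf("duplicate tRNA species name(s): %s",
                  paste(unique(df$name[duplicated(df$name)]), collapse = ", ")))
  if (!is.list(df$decoded_codons))
    df$decoded_codons <- strsplit(gsub(" ", "", df$decoded_codons), ",")
  df$decoded_codons <- lapply(df$decoded_codons, function(cv) {
    cv <- assert_codon(cv, "decoded_codons")
    if (length(cv) == 0) abort("every tRNA species must decode at least one codon")
    unique(cv)
  })
  df$gene_copy_number <- as.integer(df$gene_copy_number)
  if (any(df$gene_copy_number < 1)) abort("gene_copy_number must be >= 1")
  if (is.null(df[["relative_abundance"]]))
    df$relative_abundance <- as.numeric(df$gene_copy_number)
  if (any(df$relative_abundance <= 0))
    abort("relative_abundance must be positive (depletion is applied at rate build)")
  class(df) <- c("trna_tbl", setdiff(class(df), "trna_tbl"))
  df
}

#' Read / write a tRNA complement as TSV
#'
#' Columns: name, anticodon, amino_acid, gene_copy_number, relative_abundance,
#' decoded_codons (comma-separated). Lines starting with `#` are metadata.
#'
#' @param path file path.
#' @return [read_trna_table()] returns a `trna_tbl`.
#' @export
read_trna_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df$gene_copy_number <- as.integer(df$gene_copy_number)
  if (!is.null(df[["relative_abundance"]]))
    df$relative_abundance <- as.numeric(df$relative_abundance)
  trna_table(df)
}

#' @param trna a `trna_tbl`.
#' @rdname read_trna_table
#' @export
write_trna_table <- function(trna, path) {
  out <- trna
  out$decoded_codons <- vapply(trna$decoded_codons, paste, character(1), collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Classify tRNA species by gene copy number
#'
#' Single-gene-copy tRNAs (GCN = 1) are the scarce species whose depletion
#' the screens probe; multicopy species with GCN > 4 are classed abundant.
#'
#' @param trna a `trna_tbl`.
#' @return The table with an `abundance_class` factor column
#'   (`single_copy`, `intermediate`, `abundant`).
#' @export
classify_abundance <- function(trna) {
  gcn <- trna$gene_copy_number
  cls <- ifelse(gcn == 1, "single_copy", ifelse(gcn > 4, "abundant", "intermediate"))
  trna$abundance_class <- factor(cls, levels = c("single_copy", "intermediate", "abundant"))
  trna
}

#' Specify an in silico tRNA depletion
#'
#' @param trna_name name of the species to deplete.
#' @param factor multiplicative abundance factor in (0, 1]; the default 0.25
#'   mimics a mutant with ~25% of the wild-type tRNA level.
#' @return A `depletion_spec` object.
#' @export
depletion <- function(trna_name, factor = 0.25) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    abort("depletion `factor` must be a scalar in (0, 1]")
  structure(list(trna_name = trna_name, factor = factor), class = "depletion_spec")
}

as_depletion_list <- function(x) {
  if (is.null(x)) return(list())
  if (inherits(x, "depletion_spec")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "depletion_spec"))) return(x)
  abort("`depletions` must be NULL, a depletion(), or a list of depletion()s")
}

#' Build per-codon tRNA-arrival rates
#'
#' The arrival rate of the cognate tRNA at a codon is proportional to the
#' concentration of the decoding species, `k(codon) = c * sum(abundance)`
#' over all species decoding that codon (additive iso-acceptor decoding).
#' A depletion multiplies one species' abundance by its factor before the
#' sum. Translocation (`gamma = 35` per second) and termination
#' (`beta = gamma`, not limiting) complete the rate set.
#'
#' @param trna a `trna_tbl`.
#' @param depletions a [depletion()] or list of them, or `NULL` for wild type.
#' @param gamma translocation rate, 1/s.
#' @param beta termination rate, 1/s; defaults to `gamma`.
#' @param scaling proportionality constant `c` in 1/s per abundance unit.
#'   The default 3/s puts a single-gene-copy codon at 3/s (a strong,
#'   arrival-limited pause: ~2.6 codons/s net) while abundantly decoded
#'   codons (abundance 5-16) run at 15-48/s, fast against both the
#'   translocation rate and physiological initiation demand - so wild-type
#'   translation stays initiation-dominated and only rare codons can seed
#'   queues.
#' @return A `rate_table` object with fields `k` (named numeric, codon ->
#'   rate), `gamma`, `beta`, `scaling`.
#' @export
build_rate_table <- function(trna, depletions = NULL, gamma = 35,
                             beta = gamma, scaling = NULL) {
  if (gamma <= 0 || beta <= 0) abort("gamma and beta must be positive")
  depletions <- as_depletion_list(depletions)
  eff <- trna$relative_abundance
  for (d in depletions) {
    i <- match(d$trna_name, trna$name)
    if (is.na(i)) abort(sprintf("unknown tRNA species in depletion: %s", d$trna_name))
    eff[i] <- eff[i] * d$factor
  }
  codons <- sort(unique(unlist(trna$decoded_codons)))
  ab <- vapply(codons, function(cd) {
    sum(eff[vapply(trna$decoded_codons, function(s) cd %in% s, logical(1))])
  }, numeric(1))
  if (is.null(scaling)) scaling <- 3
  k <- scaling * ab
  if (any(k <= 0)) abort("all codon arrival rates must be positive")
  structure(list(k = setNames(k, codons), gamma = gamma, beta = beta,
                 scaling = scaling),
            class = "rate_table")
}

#' @export
#' @method print rate_table
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %d codons | gamma = %g /s, beta = %g /s, c = %.4g\n",
              length(x$k), x$gamma, x$beta, x$scaling))
  cat(sprintf("  k: min %.3g, median %.3g, max %.3g /s\n",
              min(x$k), stats::median(x$k), max(x$k)))
  invisible(x)
}

#' @export
tidy.rate_table <- function(x, ...) {
  tibble(codon = names(x$k), k = unname(x$k))
}

#' Check that a tRNA complement covers a transcriptome
#'
#' Every codon occurring in the coding sequences must be decoded by at least
#' one species; otherwise the simulation would stall forever at that codon.
#'
#' @param trna a `trna_tbl`.
#' @param cds a [cds_table()] tibble.
#' @return `TRUE` invisibly, or an error naming the uncovered codon(s).
#' @export
check_coverage <- function(trna, cds) {
  used <- unique(unlist(cds$codons))
  covered <- unique(unlist(trna$decoded_codons))
  missing <- setdiff(used, covered)
  if (length(missing) > 0)
    abort(sprintf("codon(s) not decoded by any tRNA species: %s",
                  paste(sort(missing), collapse = ", ")))
  invisible(TRUE)
}

#' Codons decoded exclusively by single-gene-copy tRNAs
#'
#' The default working definition of a "rare codon": every species decoding
#' it has gene copy number 1.
#'
#' @param trna a `trna_tbl`.
#' @return Character vector of rare codons (possibly empty).
#' @export
rare_codons <- function(trna) {
  codons <- sort(unique(unlist(trna$decoded_codons)))
  keep <- vapply(codons, function(cd) {
    dec <- vapply(trna$decoded_codons, function(s) cd %in% s, logical(1))
    all(trna$gene_copy_number[dec] == 1)
  }, logical(1))
  codons[keep]
}

# per-site arrival rates for one codon vector; errors name missing codons
site_rates <- function(codons, rates) {
  k <- rates$k[codons]
  if (anyNA(k))
    abort(sprintf("no arrival rate for codon(s): %s",
                  paste(sort(unique(codons[is.na(k)])), collapse = ", ")))
  unname(k)
}
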