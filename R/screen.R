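#' Transcriptome-wide wild-type vs tRNA-depleted translation screen
#'
#' For each ORF, runs one wild-type and one depleted Gillespie simulation
#' with the same per-ORF seed (paired design: with a depletion factor of 1
#' the two runs are bit-identical and every ratio is exactly 1, so ratio
#' noise is attributable to the depletion alone), forms the translation-rate
#' ratio `J_depleted / J_wildtype`, and calls an ORF sensitive when the
#' ratio falls below the threshold (default 0.5, i.e. at least 2-fold
#' down-regulated).
#'
#' @param cds a [cds_table()] transcriptome.
#' @param trna a [trna_table()] complement.
#' @param depl a [depletion()] specification.
#' @param alpha scalar initiation rate or per-ORF tibble (`orf_id`, `alpha`).
#' @param threshold sensitivity threshold on the ratio.
#' @param seed master seed; per-ORF seeds derive from it and the `orf_id`.
#' @param config a [sim_config()].
#' @param gamma,beta,scaling passed to [build_rate_table()].
#' @return A `tasep_screen` tibble, one row per simulated ORF: `orf_id`,
#'   `alpha`, `J_wt`, `J_wt_se`, `J_dep`, `J_dep_se`, `ratio`, `ratio_se`,
#'   `sensitive`. ORFs shorter than the footprint are skipped with a warning
#'   and listed in the `skipped` attribute.
#' @export
run_screen <- function(cds, trna, depl, alpha = 0.3, threshold = 0.5,
                       seed = 1L, config = sim_config(collect_density = FALSE),
                       gamma = 35, beta = gamma, scaling = NULL) {
  check_coverage(trna, cds)
  rates_wt <- build_rate_table(trna, NULL, gamma = gamma, beta = beta, scaling = scaling)
  rates_dep <- build_rate_table(trna, depl, gamma = gamma, beta = beta, scaling = scaling)

  short <- cds$length < config$footprint
  if (any(short)) {
    warn(sprintf("skipping %d ORF(s) shorter than the %d-codon footprint: %s",
                 sum(short), config$footprint,
                 paste(head(cds$orf_id[short], 5), collapse = ", ")))
  }
  kept <- cds[!short, ]
  alphas <- resolve_alphas(kept$orf_id, alpha)
  rows <- purrr::map(seq_len(nrow(kept)), function(i) {
    s <- derive_seed(seed, kept$orf_id[i])
    wt <- simulate_orf(kept$codons[[i]], rates_wt, alphas[i], seed = s, config = config)
    dp <- simulate_orf(kept$codons[[i]], rates_dep, alphas[i], seed = s, config = config)
    screen_row(kept$orf_id[i], alphas[i], wt, dp)
  })
  if (length(rows) == 0) {
    out <- screen_row("x", 1, list(J = 1, J_se = 0), list(J = 1, J_se = 0))[0, ]
  } else {
    out <- dplyr::bind_rows(rows)
  }
  out$sensitive <- out$ratio < threshold
  attr(out, "threshold") <- threshold
  attr(out, "depletion") <- depl
  attr(out, "skipped") <- cds$orf_id[short]
  class(out) <- c("tasep_screen", class(out))
  out
}

screen_row <- function(orf_id, alpha, wt, dp) {
  ratio <- dp$J / wt$J
  # first-order error propagation on the ratio of two independent currents
  ratio_se <- ratio * sqrt((wt$J_se / wt$J)^2 + (dp$J_se / dp$J)^2)
  tibble(orf_id = orf_id, alpha = alpha,
         J_wt = wt$J, J_wt_se = wt$J_se,
         J_dep = dp$J, J_dep_se = dp$J_se,
         ratio = ratio, ratio_se = ratio_se)
}

#' Depleted/wild-type translation-rate ratio across an initiation-rate grid
#'
#' Probes whether an mRNA is initiation- or elongation-limited: for a
#' tRNA-sensitive mRNA the ratio is depressed at physiological initiation
#' rates (ribosome queues at depleted codons back up to the 5' end) and
#' tends to 1 as the initiation rate is decreased, because initiation, not
#' elongation, becomes the bottleneck in both conditions.
#'
#' @param cds a single-row [cds_table()] or a codon character vector.
#' @param alphas grid of initiation rates (any order; results are sorted
#'   increasing).
#' @inheritParams run_screen
#' @return An `alpha_scan` tibble: `orf_id`, `alpha`, `J_wt`, `J_wt_se`,
#'   `J_dep`, `J_dep_se`, `ratio`, `ratio_se`, sorted by increasing `alpha`.
#' @export
alpha_scan <- function(cds, trna, depl, alphas, seed = 1L,
                       config = sim_config(collect_density = FALSE),
                       gamma = 35, beta = gamma, scaling = NULL) {
  if (length(alphas) == 0 || any(alphas <= 0))
    abort("`alphas` must be a nonempty grid of positive rates")
  if (is.data.frame(cds)) {
    orf_id <- cds$orf_id[1]
    codons <- cds$codons[[1]]
  } else {
    orf_id <- "orf"
    codons <- canonical_codon(cds)
  }
  rates_wt <- build_rate_table(trna, NULL, gamma = gamma, beta = beta, scaling = scaling)
  rates_dep <- build_rate_table(trna, depl, gamma = gamma, beta = beta, scaling = scaling)
  alphas <- sort(unique(alphas))
  rows <- purrr::map(alphas, function(a) {
    s <- derive_seed(seed, paste0(orf_id, "@", format(a, digits = 12)))
    wt <- simulate_orf(codons, rates_wt, a, seed = s, config = config)
    dp <- simulate_orf(codons, rates_dep, a, seed = s, config = config)
    screen_row(orf_id, a, wt, dp)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("alpha_scan", class(out))
  out
}

#' Compare 5' ribosome-density profiles between conditions and
#' initiation rates
#'
#' Runs wild-type and depleted simulations at a high (physiological) and a
#' low initiation rate and contrasts the per-codon A-site density over a 5'
#' window. A queue-prone mRNA shows a depleted-minus-wild-type density
#' excess near the 5' end at the high rate that dissipates at the low rate.
#'
#' @inheritParams alpha_scan
#' @param alpha_high,alpha_low the two initiation rates (1/s).
#' @param window codon indices of the 5' window.
#' @return A `density_compare` object: `$profiles` (long tibble: condition,
#'   alpha_level, alpha, codon_index, rho, rho_se), `$differential`
#'   (depleted - wild-type per codon, with propagated SE), and `$summary`
#'   (mean window differential per alpha level, with SE from batch means).
#' @export
density_compare <- function(cds, trna, depl, alpha_high = 0.3,
                            alpha_low = 0.05, window = 1:30, seed = 1L,
                            config = sim_config(), gamma = 35, beta = gamma,
                            scaling = NULL) {
  if (is.data.frame(cds)) {
    orf_id <- cds$orf_id[1]
    codons <- cds$codons[[1]]
  } else {
    orf_id <- "orf"
    codons <- canonical_codon(cds)
  }
  if (any(window < 1) || any(window > length(codons)))
    abort("window out of range for this coding sequence")
  config$collect_density <- TRUE
  rates_wt <- build_rate_table(trna, NULL, gamma = gamma, beta = beta, scaling = scaling)
  rates_dep <- build_rate_table(trna, depl, gamma = gamma, beta = beta, scaling = scaling)

  runs <- list()
  for (lev in c("high", "low")) {
    a <- if (lev == "high") alpha_high else alpha_low
    s <- derive_seed(seed, paste0(orf_id, "@", lev))
    runs[[paste0("wild_type.", lev)]] <-
      simulate_orf(codons, rates_wt, a, seed = s, config = config)
    runs[[paste0("depleted.", lev)]] <-
      simulate_orf(codons, rates_dep, a, seed = s, config = config)
  }
  profiles <- purrr::imap(runs, function(sim, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    dplyr::mutate(density_profile(sim, window),
                  condition = parts[1], alpha_level = parts[2],
                  alpha = sim$alpha, .before = 1)
  })
  profiles <- dplyr::bind_rows(profiles)

  differential <- purrr::map(c("high", "low"), function(lev) {
    wt <- runs[[paste0("wild_type.", lev)]]
    dp <- runs[[paste0("depleted.", lev)]]
    tibble(alpha_level = lev, alpha = wt$alpha, codon_index = window,
           diff = dp$rho[window] - wt$rho[window],
           diff_se = sqrt(wt$rho_se[window]^2 + dp$rho_se[window]^2))
  })
  differential <- dplyr::bind_rows(differential)

  summary <- purrr::map(c("high", "low"), function(lev) {
    wt <- runs[[paste0("wild_type.", lev)]]
    dp <- runs[[paste0("depleted.", lev)]]
    # SE of the window-mean density from the batch means of each run
    wt_b <- rowMeans(wt$rho_batch[, window, drop = FALSE])
    dp_b <- rowMeans(dp$rho_batch[, window, drop = FALSE])
    se <- sqrt(stats::var(wt_b) / length(wt_b) + stats::var(dp_b) / length(dp_b))
    tibble(alpha_level = lev, alpha = wt$alpha,
           mean_diff = mean(dp$rho[window] - wt$rho[window]),
           mean_diff_se = se)
  })
  summary <- dplyr::bind_rows(summary)

  structure(list(orf_id = orf_id, window = window, profiles = profiles,
                 differential = differential, summary = summary),
            class = "density_compare")
}

#' @export
#' @method print density_compare
print.density_compare <- function(x, ...) {
  cat(sprintf("<density_compare> %s, codons %d-%d\n", x$orf_id,
              min(x$window), max(x$window)))
  print(x$summary)
  invisible(x)
}

#' @export
glance.density_compare <- function(x, ...) x$summary

#' Deplete every tRNA species in turn and screen the transcriptome
#'
#' The depletion survey: one full [run_screen()] per tRNA species at the
#' given factor, e.g. over all 42 species of a cytoplasmic complement.
#'
#' @inheritParams run_screen
#' @param factor depletion factor applied to each species in turn.
#' @param trna_names species to survey (default: all in the table).
#' @return A tibble, one row per (tRNA species, ORF), with the
#'   [run_screen()] columns plus `trna_name`.
#' @export
multi_trna_screen <- function(cds, trna, factor = 0.25, alpha = 0.3,
                              threshold = 0.5, seed = 1L,
                              config = sim_config(collect_density = FALSE),
                              trna_names = trna$name, gamma = 35,
                              beta = gamma, scaling = NULL) {
  rows <- purrr::map(trna_names, function(nm) {
    scr <- run_screen(cds, trna, depletion(nm, factor), alpha = alpha,
                      threshold = threshold, seed = seed, config = config,
                      gamma = gamma, beta = beta, scaling = scaling)
    dplyr::mutate(as_tibble(scr), trna_name = nm, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trna_survey", class(out))
  out
}

#' Summarise a depletion survey per tRNA species
#'
#' @param survey output of [multi_trna_screen()].
#' @param trna the complement used (for gene copy numbers).
#' @return One row per species: `trna_name`, `gene_copy_number`,
#'   `abundance_class`, `n_orfs`, `n_sensitive`, `max_abs_dev` (largest
#'   `|ratio - 1|`).
#' @export
summarise_survey <- function(survey, trna) {
  cls <- classify_abundance(trna)
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(survey), .data$trna_name),
    n_orfs = dplyr::n(),
    n_sensitive = sum(.data$sensitive),
    max_abs_dev = max(abs(.data$ratio - 1)),
    .groups = "drop")
  dplyr::left_join(out,
                   dplyr::select(as_tibble(cls), trna_name = "name",
                                 "gene_copy_number", "abundance_class"),
                   by = "trna_name")
}

#' Correlate rare-codon composition with depletion sensitivity
#'
#' Ordinary least squares of the translation-efficiency ratio
#' (depleted/wild-type) on the focal rare-codon ratio over the `top_n` most
#' sensitive ORFs; a negative slope means that mRNAs enriched in the focal
#' rare codon (relative to other rare codons) are the more down-regulated.
#'
#' @param records a [run_screen()] result.
#' @param stats a per-ORF composition tibble with `orf_id` and `ratio` (from
#'   [rare_codon_ratio()]) or `rare_codon_ratio` (from [codon_stats()]).
#' @param top_n number of most-sensitive ORFs to use.
#' @return A one-row tibble: `n_used`, `n_excluded`, `pearson_r`,
#'   `r_squared`, `slope`, `intercept`, `p_value`.
#' @export
correlate_sensitivity <- function(records, stats, top_n = 90) {
  comp_col <- if ("rare_codon_ratio" %in% names(stats)) "rare_codon_ratio" else "ratio"
  comp <- tibble(orf_id = stats$orf_id, composition = stats[[comp_col]])
  df <- dplyr::inner_join(
    dplyr::select(as_tibble(records), "orf_id", efficiency_ratio = "ratio"),
    comp, by = "orf_id")
  usable <- is.finite(df$composition) & is.finite(df$efficiency_ratio)
  n_excluded <- sum(!usable)
  df <- df[usable, ]
  df <- head(df[order(df$efficiency_ratio), ], top_n)
  if (nrow(df) < 3) abort("fewer than 3 ORFs with defined ratio and composition")
  if (sd(df$composition) == 0 || sd(df$efficiency_ratio) == 0)
    abort("correlation undefined: zero variance in composition or ratio")
  fit <- lm(efficiency_ratio ~ composition, data = df)
  r <- cor(df$composition, df$efficiency_ratio)
  tibble(n_used = nrow(df), n_excluded = n_excluded,
         pearson_r = r, r_squared = r^2,
         slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
         p_value = summary(fit)$coefficients[2, 4])
}
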