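#' Simulation configuration
#'
#' Controls the Gillespie run: ribosome footprint, burn-in rule, and the
#' measurement target. Burn-in discards
#' `max(burn_in_multiplier * T1, time to the first burn_in_terminations)`,
#' where `T1 = 1/alpha + sum(1/k_i) + (L-1)/gamma + 1/beta` is the
#' single-ribosome transit time. Measurement then runs in equal-length
#' batches (sized from a short pilot estimate of `J`) until at least
#' `target_terminations` proteins have been released or `max_time` simulated
#' seconds have elapsed, whichever comes first; the batch means give the
#' standard error of `J`.
#'
#' @param footprint ribosome footprint in codons (9: the physical width).
#' @param target_terminations measurement target, proteins released.
#' @param max_time measurement cap, simulated seconds.
#' @param burn_in_multiplier multiples of `T1` discarded.
#' @param burn_in_terminations terminations that must also have occurred
#'   before measurement starts.
#' @param n_batches minimum number of measurement batches.
#' @param collect_density keep per-batch density profiles (needed for density
#'   standard errors).
#' @return A `sim_config` object.
#' @export
sim_config <- function(footprint = 9L, target_terminations = 1000,
                       max_time = 1e5, burn_in_multiplier = 10,
                       burn_in_terminations = 20L, n_batches = 10L,
                       collect_density = TRUE) {
  if (footprint < 1) abort("footprint must be >= 1 codon")
  if (target_terminations < 1 || max_time <= 0) abort("measurement target must be positive")
  if (n_batches < 2) abort("need at least 2 batches for a standard error")
  structure(list(footprint = as.integer(footprint),
                 target_terminations = target_terminations,
                 max_time = max_time,
                 burn_in_multiplier = burn_in_multiplier,
                 burn_in_terminations = as.integer(burn_in_terminations),
                 n_batches = as.integer(n_batches),
                 collect_density = isTRUE(collect_density)),
            class = "sim_config")
}

#' Simulate translation of a single coding sequence
#'
#' Continuous-time Gillespie simulation of the two-state TASEP: ribosomes
#' initiate at rate `alpha` when the first `footprint` codons are free, wait
#' for the cognate tRNA at rate `k_i`, translocate at rate `gamma` when the
#' codon ahead of the footprint is free, and terminate from the last sense
#' codon at rate `beta`.
#'
#' @param codons character vector of sense codons (the lattice), or a
#'   single-row [cds_table()].
#' @param rates a [build_rate_table()] object.
#' @param alpha initiation rate, 1/s.
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param config a [sim_config()].
#' @return A `tasep_sim` object: translation rate `J` (proteins/s) with
#'   batch-means standard error `J_se`, per-codon A-site density `rho` with
#'   `rho_se`, `mean_ribosomes`, event counts, `measured_time`, and the seed.
#' @export
simulate_orf <- function(codons, rates, alpha, seed = 1L, config = sim_config()) {
  orf_id <- NA_character_
  if (is.data.frame(codons)) {
    if (nrow(codons) != 1) abort("pass a single-row cds_tbl or a codon vector")
    orf_id <- codons$orf_id
    codons <- codons$codons[[1]]
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    abort("alpha must be a positive scalar initiation rate")
  L <- length(codons)
  if (L < config$footprint)
    abort(sprintf("lattice of %d codons is shorter than the %d-codon footprint",
                  L, config$footprint))
  k <- site_rates(codons, rates)
  t1 <- 1 / alpha + sum(1 / k) + (L - 1) / rates$gamma + 1 / rates$beta
  res <- .simulate_tasep_cpp(k, alpha, rates$gamma, rates$beta,
                             config$footprint,
                             config$burn_in_multiplier * t1,
                             config$burn_in_terminations,
                             config$target_terminations, config$max_time,
                             config$n_batches, as.double(seed))
  rho_se <- apply(res$rho_batch, 2, sd) / sqrt(res$n_batches)
  out <- structure(list(
    orf_id = orf_id, L = L, alpha = alpha,
    footprint = config$footprint, seed = as.integer(seed),
    J = res$J, J_se = res$J_se,
    rho = res$rho, rho_se = rho_se,
    rho_batch = if (config$collect_density) res$rho_batch else NULL,
    mean_ribosomes = res$mean_ribosomes,
    n_initiations = res$n_initiations,
    n_terminations = res$n_terminations,
    measured_time = res$measured_time,
    n_batches = res$n_batches,
    ribosomes_at_end = res$ribosomes_on_lattice
  ), class = "tasep_sim")
  validate_sim_result(out)
  out
}

#' Assert the conservation invariants of a simulation result
#'
#' Checks that every density lies in `[0, 1]`, that the densities sum to the
#' mean ribosome number, that the initiation/termination counts balance up
#' to the ribosomes still on the lattice, and that `J` does not exceed
#' `alpha` beyond its own counting noise (the measured current fluctuates
#' around `alpha` in the initiation-limited regime, so the bound is
#' statistical, at three standard errors).
#'
#' @param sim a `tasep_sim` object.
#' @return `sim` invisibly; errors if an invariant is violated.
#' @export
validate_sim_result <- function(sim) {
  eps <- 1e-8
  if (any(sim$rho < -eps) || any(sim$rho > 1 + eps))
    abort("density invariant violated: rho outside [0, 1]")
  if (abs(sum(sim$rho) - sim$mean_ribosomes) > 1e-6 * max(1, sim$mean_ribosomes))
    abort("density invariant violated: sum(rho) != mean ribosome count")
  max_onboard <- floor((sim$L - 1) / sim$footprint) + 1
  if (abs(sim$n_initiations - sim$n_terminations) > max_onboard)
    abort("flux invariant violated: initiation and termination counts diverge")
  if (sim$J > sim$alpha + 3 * sim$J_se + eps)
    abort("current invariant violated: J exceeds alpha beyond noise")
  invisible(sim)
}

#' @export
#' @method print tasep_sim
print.tasep_sim <- function(x, ...) {
  cat(sprintf("<tasep_sim>%s L = %d codons, alpha = %g /s\n",
              if (is.na(x$orf_id)) "" else paste0(" ", x$orf_id, ","), x$L, x$alpha))
  cat(sprintf("  J = %.4g +/- %.2g proteins/s  (%d terminations in %.4g s, %d batches)\n",
              x$J, x$J_se, x$n_terminations, x$measured_time, x$n_batches))
  cat(sprintf("  mean ribosomes on mRNA = %.3g\n", x$mean_ribosomes))
  invisible(x)
}

#' @describeIn simulate_orf per-codon A-site density as a tibble.
#' @param x a `tasep_sim` object.
#' @param ... unused.
#' @export
tidy.tasep_sim <- function(x, ...) {
  tibble(codon_index = seq_len(x$L), rho = x$rho, rho_se = x$rho_se)
}

#' @describeIn simulate_orf one-row run summary.
#' @export
glance.tasep_sim <- function(x, ...) {
  tibble(orf_id = x$orf_id, L = x$L, alpha = x$alpha, J = x$J, J_se = x$J_se,
         mean_ribosomes = x$mean_ribosomes,
         n_initiations = x$n_initiations, n_terminations = x$n_terminations,
         measured_time = x$measured_time, n_batches = x$n_batches,
         seed = x$seed)
}

#' Slice a density profile
#'
#' @param sim a `tasep_sim` object.
#' @param window integer vector of codon indices within `1..L`.
#' @return A tibble with `codon_index`, `rho`, `rho_se` over the window.
#' @export
density_profile <- function(sim, window = seq_len(sim$L)) {
  if (any(window < 1) || any(window > sim$L))
    abort(sprintf("window must lie within 1..%d", sim$L))
  tidy(sim)[window, ]
}

#' Simulate translation across a transcriptome
#'
#' Data-frame-first wrapper over [simulate_orf()]: one independent, seeded
#' simulation per ORF. Per-ORF seeds derive deterministically from the master
#' seed and the `orf_id`, so results do not depend on row order.
#'
#' @param cds a [cds_table()] tibble.
#' @param rates a [build_rate_table()] object.
#' @param alpha scalar initiation rate, or a tibble with `orf_id`, `alpha`.
#' @param seed master seed.
#' @param config a [sim_config()].
#' @return A tibble, one row per ORF: `orf_id`, `alpha`, `J`, `J_se`,
#'   `mean_ribosomes`, `n_terminations`, `measured_time`, `seed`, and a
#'   `density` list-column of per-codon tibbles.
#' @export
simulate_translation <- function(cds, rates, alpha = 0.3, seed = 1L,
                                 config = sim_config()) {
  alphas <- resolve_alphas(cds$orf_id, alpha)
  rows <- purrr::map(seq_len(nrow(cds)), function(i) {
    s <- derive_seed(seed, cds$orf_id[i])
    sim <- simulate_orf(cds$codons[[i]], rates, alphas[i], seed = s, config = config)
    g <- glance(sim)
    g$orf_id <- cds$orf_id[i]
    g$density <- list(tidy(sim))
    g
  })
  dplyr::bind_rows(rows)
}

# scalar alpha, or per-ORF lookup table (orf_id, alpha) with default fill
resolve_alphas <- function(orf_ids, alpha, default = 0.3) {
  if (is.numeric(alpha) && length(alpha) == 1) {
    if (alpha <= 0) abort("alpha must be positive")
    return(rep(alpha, length(orf_ids)))
  }
  if (is.data.frame(alpha)) {
    a <- alpha$alpha[match(orf_ids, alpha$orf_id)]
    a[is.na(a)] <- default
    if (any(a <= 0)) abort("alpha must be positive for every ORF")
    return(a)
  }
  abort("`alpha` must be a positive scalar or a tibble with orf_id and alpha")
}
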