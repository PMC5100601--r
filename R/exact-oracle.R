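#' Enumerate the states of the two-state extended-particle TASEP
#'
#' A state is an ordered set of ribosomes at A-site positions
#' `p_1 < p_2 < ... < p_m` with `p_{j+1} >= p_j + footprint` (disjoint
#' footprints, truncated at the last codon) and an internal flag per ribosome
#' (awaiting tRNA / tRNA bound). The empty lattice is included. Exhaustive
#' enumeration is only feasible on small lattices; the footprint can be set
#' below 9 to exercise multi-ribosome interactions at small `L`.
#'
#' @param L lattice length in codons.
#' @param footprint ribosome footprint in codons.
#' @param max_ribosomes cap on simultaneous ribosomes (default: no cap).
#' @param cap maximum admissible number of states.
#' @return A list of states; each state is a list with integer `pos`
#'   (increasing) and logical `bound` of the same length.
#' @export
enumerate_states <- function(L, footprint, max_ribosomes = Inf, cap = 2e5) {
  placements <- list(integer(0))
  grow <- function(prefix, min_p) {
    out <- list()
    if (length(prefix) >= max_ribosomes || min_p > L) return(out)
    for (p in seq(min_p, L)) {
      withp <- c(prefix, p)
      out <- c(out, list(withp), grow(withp, p + footprint))
      if (length(out) > cap) abort("state space too large for exact solve")
    }
    out
  }
  if (L >= 1) placements <- c(placements, grow(integer(0), 1L))
  states <- list()
  for (pl in placements) {
    m <- length(pl)
    if (m == 0) {
      states <- c(states, list(list(pos = integer(0), bound = logical(0))))
      next
    }
    for (mask in 0:(2^m - 1)) {
      bound <- as.logical(bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L))
      states <- c(states, list(list(pos = pl, bound = bound)))
    }
    if (length(states) > cap) abort("state space too large for exact solve")
  }
  states
}

state_key <- function(s) {
  if (length(s$pos) == 0) return("empty")
  paste(s$pos, as.integer(s$bound), sep = ":", collapse = ";")
}

#' Exact stationary translation current on a small lattice
#'
#' Builds the generator of the continuous-time Markov chain over all
#' ribosome configurations, solves the global balance equations (sparse LU,
#' one balance row replaced by the normalisation), and reads off the exact
#' current `J = beta * P(bound ribosome at the last codon)` together with
#' the marginal A-site densities. Used as the independent verification
#' oracle for the Gillespie engine.
#'
#' @param codons character vector of sense codons, or a numeric vector of
#'   per-site arrival rates `k`.
#' @param rates a [build_rate_table()] (ignored when `codons` is numeric,
#'   except for `gamma`/`beta`); alternatively pass `gamma` and `beta`.
#' @param alpha initiation rate, 1/s.
#' @param footprint ribosome footprint in codons.
#' @param gamma,beta translocation and termination rates when `codons` is a
#'   bare rate vector.
#' @param cap maximum admissible number of states.
#' @return An `exact_solution`: `J_exact`, `rho_exact` (per-codon A-site
#'   probabilities), `mean_ribosomes`, `p_init_free` (probability that the
#'   first `footprint` codons are free), `n_states`, and the stationary
#'   distribution `pi`.
#' @export
exact_current <- function(codons, rates = NULL, alpha, footprint = 9,
                          gamma = NULL, beta = NULL, cap = 2e5) {
  if (is.character(codons)) {
    k <- site_rates(canonical_codon(codons), rates)
  } else {
    k <- as.numeric(codons)
  }
  if (!is.null(rates)) {
    if (is.null(gamma)) gamma <- rates$gamma
    if (is.null(beta)) beta <- rates$beta
  }
  if (is.null(gamma)) gamma <- 35
  if (is.null(beta)) beta <- gamma
  L <- length(k)
  if (alpha <= 0 || gamma <= 0 || beta <= 0 || any(k <= 0))
    abort("all rates must be positive")
  if (L < footprint) abort("lattice shorter than the ribosome footprint")

  states <- enumerate_states(L, footprint, cap = cap)
  n <- length(states)
  idx <- setNames(seq_len(n), vapply(states, state_key, character(1)))

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(i, s2, r) {
    j <- idx[[state_key(s2)]]
    from <<- c(from, i); to <<- c(to, j); rate <<- c(rate, r)
  }
  for (i in seq_len(n)) {
    s <- states[[i]]
    m <- length(s$pos)
    # initiation: codons 1..footprint free <=> trailing ribosome beyond them
    if (m == 0 || s$pos[1] > footprint)
      add(i, list(pos = c(1L, s$pos), bound = c(FALSE, s$bound)), alpha)
    for (j in seq_len(m)) {
      p <- s$pos[j]
      if (!s$bound[j]) {
        b <- s$bound; b[j] <- TRUE
        add(i, list(pos = s$pos, bound = b), k[p])
      } else if (p == L) {
        add(i, list(pos = s$pos[-j], bound = s$bound[-j]), beta)
      } else {
        ahead_free <- p + footprint > L ||
          j == m || s$pos[j + 1] > p + footprint
        if (ahead_free) {
          pos <- s$pos; pos[j] <- p + 1L
          b <- s$bound; b[j] <- FALSE
          add(i, list(pos = pos, bound = b), gamma)
        }
      }
    }
  }
  Q <- Matrix::sparseMatrix(i = from, j = to, x = rate, dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  A <- Matrix::t(Q)
  A[n, ] <- 1  # normalisation replaces one balance row
  b_rhs <- c(rep(0, n - 1), 1)
  pi_hat <- as.numeric(Matrix::solve(A, b_rhs))
  if (any(pi_hat < -1e-10) || abs(sum(pi_hat) - 1) > 1e-10)
    abort("ill-conditioned stationary solve")
  pi_hat <- pmax(pi_hat, 0)

  term_states <- vapply(states, function(s) {
    m <- length(s$pos); m > 0 && s$pos[m] == L && s$bound[m]
  }, logical(1))
  rho <- numeric(L)
  for (i in seq_len(n))
    for (p in states[[i]]$pos) rho[p] <- rho[p] + pi_hat[i]
  init_free <- vapply(states, function(s)
    length(s$pos) == 0 || s$pos[1] > footprint, logical(1))

  structure(list(
    J_exact = beta * sum(pi_hat[term_states]),
    rho_exact = rho,
    mean_ribosomes = sum(rho),
    p_init_free = sum(pi_hat[init_free]),
    n_states = n,
    pi = pi_hat
  ), class = "exact_solution")
}

#' @export
#' @method print exact_solution
print.exact_solution <- function(x, ...) {
  cat(sprintf("<exact_solution> %d states | J = %.6g proteins/s, mean ribosomes = %.4g\n",
              x$n_states, x$J_exact, x$mean_ribosomes))
  invisible(x)
}

#' Renewal closed form for the one-ribosome-at-a-time lattice
#'
#' When `L == footprint` at most one ribosome fits, and translation is a
#' renewal process: `J = 1 / (1/alpha + sum(1/k_i) + (L-1)/gamma + 1/beta)`.
#'
#' @param k per-site arrival rates.
#' @param alpha initiation rate.
#' @param gamma,beta translocation and termination rates.
#' @return The renewal current.
#' @export
renewal_current <- function(k, alpha, gamma = 35, beta = gamma) {
  1 / (1 / alpha + sum(1 / k) + (length(k) - 1) / gamma + 1 / beta)
}
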