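# Law-of-mass-action sequestration equilibria: one hub enzyme binding one or
# several partner enzymes with independent 1:1 sites. Concentrations are held
# in mol/L throughout.

#' Define a one-hub binding equilibrium system
#'
#' A system consists of a hub protein at total concentration `hub_total`
#' and `N >= 0` partner proteins, each binding the hub independently with
#' 1:1 stoichiometry at its own dissociation constant. Partners are assumed
#' not to bind each other and not to compete for the same hub surface
#' (independent sites).
#'
#' @param hub hub species name.
#' @param hub_total total hub concentration (mol/L), `>= 0`.
#' @param partners character vector of partner names (unique, distinct from
#'   the hub).
#' @param partner_totals total partner concentrations (mol/L), one per
#'   partner.
#' @param kds dissociation constants (mol/L), one per partner, all `> 0`.
#' @return an object of class `equilibrium_system`.
#' @seealso [solve_competitive()], [titration_scan()]
#' @export
#' @examples
#' equilibrium_system("DHFR", 5e-8, c("PurH", "GlyA"), c(2e-7, 1.66e-5),
#'                    kds = c(3e-6, 8e-6))
equilibrium_system <- function(hub, hub_total, partners = character(),
                               partner_totals = numeric(),
                               kds = numeric()) {
  stopifnot(is.character(hub), length(hub) == 1L)
  check_number(hub_total, "hub_total", lower = 0)
  n <- length(partners)
  if (length(partner_totals) != n || length(kds) != n) {
    stop("`partners`, `partner_totals` and `kds` must have equal length",
         call. = FALSE)
  }
  if (n > 0) {
    check_numeric_vec(partner_totals, "partner_totals", lower = 0)
    check_numeric_vec(kds, "kds", lower = 0, strict = TRUE)
    if (anyDuplicated(partners) || hub %in% partners) {
      stop("species names must be unique and partners distinct from the hub",
           call. = FALSE)
    }
  }
  structure(
    list(hub = hub, hub_total = hub_total,
         partners = data.frame(name = as.character(partners),
                               total = as.numeric(partner_totals),
                               kd = as.numeric(kds),
                               stringsAsFactors = FALSE)),
    class = "equilibrium_system")
}

#' @export
print.equilibrium_system <- function(x, ...) {
  cat(sprintf("Equilibrium system: hub %s at %.3g M, %d partner(s)\n",
              x$hub, x$hub_total, nrow(x$partners)))
  if (nrow(x$partners)) print(x$partners, row.names = FALSE)
  invisible(x)
}

new_equilibrium_state <- function(free, complex, totals) {
  structure(list(free = free, complex = complex,
                 fraction_bound = ifelse(totals > 0,
                                         (totals - free) / totals, 0),
                 totals = totals),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Equilibrium state (mol/L):\n")
  print(data.frame(species = names(x$free), total = x$totals,
                   free = x$free,
                   fraction_bound = x$fraction_bound, row.names = NULL))
  invisible(x)
}

#' Solve the pairwise hub-partner binding equilibrium
#'
#' Closed-form solution of the two-species 1:1 binding equilibrium with mass
#' conservation. With hub total \eqn{D}, partner total \eqn{P} and
#' dissociation constant \eqn{K}, the complex concentration is the smaller
#' root of \eqn{c^2 - (D+P+K)c + DP = 0}, the only root in
#' \eqn{[0, \min(D,P)]}. It is evaluated in the numerically stable form
#' \eqn{c = 2DP / (b + \sqrt{b^2 - 4DP})}, \eqn{b = D+P+K}, which avoids the
#' catastrophic cancellation of the textbook formula when \eqn{4DP \ll b^2}.
#'
#' @param hub_total total hub concentration (mol/L), `>= 0`.
#' @param partner_total total partner concentration (mol/L), `>= 0`.
#' @param kd dissociation constant (mol/L), `> 0`.
#' @param hub,partner species names used in the returned state.
#' @return an `equilibrium_state` with free concentrations, the complex
#'   concentration and the bound fraction of each species.
#' @export
#' @examples
#' # basal E. coli abundances: 50 copies DHFR, 200 copies PurH, KD ~ 3 uM
#' st <- solve_pairwise(5e-8, 2e-7, 3e-6, hub = "DHFR", partner = "PurH")
#' 100 * st$fraction_bound
solve_pairwise <- function(hub_total, partner_total, kd,
                           hub = "hub", partner = "partner") {
  check_number(hub_total, "hub_total", lower = 0)
  check_number(partner_total, "partner_total", lower = 0)
  check_number(kd, "kd", lower = 0, strict = TRUE)
  b <- hub_total + partner_total + kd
  disc <- b^2 - 4 * hub_total * partner_total
  disc <- max(disc, 0)
  cplx <- 2 * hub_total * partner_total / (b + sqrt(disc))
  free <- c(hub_total - cplx, partner_total - cplx)
  names(free) <- c(hub, partner)
  complex <- c(cplx)
  names(complex) <- partner
  totals <- c(hub_total, partner_total)
  names(totals) <- c(hub, partner)
  new_equilibrium_state(free, complex, totals)
}

#' Solve a competitive one-hub, N-partner equilibrium
#'
#' Generalizes the pairwise solution to a hub shared by several independent
#' 1:1 partners. The free hub concentration \eqn{h} solves the conservation
#' equation \eqn{h + \sum_i h P_{i,T}/(K_i + h) = H_T}, whose left side is
#' strictly increasing in \eqn{h}; the root is bracketed in \eqn{[0, H_T]}
#' and found by bisection to relative tolerance `tol`. Free partner
#' concentrations follow as \eqn{P_{i,T} K_i / (K_i + h)}.
#'
#' @param system an [equilibrium_system()].
#' @param tol relative tolerance on the free hub concentration.
#' @return an `equilibrium_state` covering the hub and all partners.
#' @export
#' @examples
#' sys <- equilibrium_system("DHFR", 5e-8, c("PurH", "GlyA"),
#'                           c(2e-7, 1.66e-5), kds = c(3e-6, 8e-6))
#' solve_competitive(sys)
solve_competitive <- function(system, tol = 1e-12) {
  stopifnot(inherits(system, "equilibrium_system"))
  H <- system$hub_total
  P <- system$partners$total
  K <- system$partners$kd
  nm <- c(system$hub, system$partners$name)
  totals <- c(H, P)
  names(totals) <- nm
  if (nrow(system$partners) == 0L || H == 0) {
    free <- totals
    complex <- rep(0, nrow(system$partners))
    names(complex) <- system$partners$name
    return(new_equilibrium_state(free, complex, totals))
  }
  bound_hub <- function(h) sum(h * P / (K + h))
  f <- function(h) h + bound_hub(h) - H
  lo <- 0
  hi <- H
  # ~60 halvings reach double precision on [0, H]; relative refinement below
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= tol * max(lo, .Machine$double.xmin)) break
  }
  h <- (lo + hi) / 2
  if (abs(f(h)) > 1e-9 * H) {
    stop(sprintf(paste0("competitive solver did not converge: residual %.3g",
                        " at free hub %.3g (hub total %.3g)"),
                 f(h), h, H), call. = FALSE)
  }
  free_p <- P * K / (K + h)
  complex <- h * P / (K + h)
  names(complex) <- system$partners$name
  free <- c(h, free_p)
  names(free) <- nm
  new_equilibrium_state(free, complex, totals)
}

#' Check internal consistency of an equilibrium state
#'
#' Verifies mass conservation (free + bound = total) for every species and
#' the law-of-mass-action relation complex = free_hub * free_partner / KD
#' for every pair, each to a relative tolerance.
#'
#' @param state an `equilibrium_state`.
#' @param system the `equilibrium_system` it was solved from (or `NULL` to
#'   check conservation only).
#' @param tol relative tolerance.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_equilibrium_state <- function(state, system = NULL, tol = 1e-9) {
  stopifnot(inherits(state, "equilibrium_state"))
  if (any(state$free < 0) || any(state$complex < 0)) {
    stop("negative concentration in state", call. = FALSE)
  }
  hub <- names(state$free)[1L]
  bound_hub <- sum(state$complex)
  scale_h <- max(state$totals[hub], .Machine$double.xmin)
  if (abs(state$free[hub] + bound_hub - state$totals[hub]) > tol * scale_h) {
    stop("hub mass conservation violated", call. = FALSE)
  }
  for (p in names(state$complex)) {
    scale_p <- max(state$totals[p], .Machine$double.xmin)
    if (abs(state$free[p] + state$complex[p] - state$totals[p]) >
        tol * scale_p) {
      stop(sprintf("mass conservation violated for %s", p), call. = FALSE)
    }
  }
  if (!is.null(system)) {
    for (i in seq_len(nrow(system$partners))) {
      p <- system$partners$name[i]
      expect <- state$free[hub] * state$free[p] / system$partners$kd[i]
      scale_c <- max(expect, state$complex[p], .Machine$double.xmin)
      if (abs(state$complex[p] - expect) > tol * scale_c) {
        stop(sprintf("mass-action relation violated for pair %s-%s",
                     hub, p), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Titrate the hub across fold-overexpression factors
#'
#' Scales the hub total concentration by each factor while holding partner
#' totals fixed, solving the competitive equilibrium at each point. This
#' emulates an overexpression titration of the hub enzyme.
#'
#' @param system an [equilibrium_system()].
#' @param fold_factors positive multipliers applied to the hub total.
#' @return a long-format data frame with columns `fold`, `species`, `role`
#'   (`"hub"`/`"partner"`), `total`, `free` and `fraction_bound`; one row per
#'   species per factor. Bound partner fractions are monotone nondecreasing
#'   in `fold`.
#' @export
#' @examples
#' sys <- equilibrium_system("DHFR", 5e-8, "PurH", 2e-7, kds = 3e-6)
#' titration_scan(sys, c(1, 10, 100, 1000))
titration_scan <- function(system, fold_factors) {
  stopifnot(inherits(system, "equilibrium_system"))
  empty <- data.frame(fold = numeric(), species = character(),
                      role = character(), total = numeric(),
                      free = numeric(), fraction_bound = numeric(),
                      stringsAsFactors = FALSE)
  if (length(fold_factors) == 0L) return(empty)
  check_numeric_vec(fold_factors, "fold_factors", lower = 0, strict = TRUE)
  rows <- lapply(fold_factors, function(f) {
    scaled <- system
    scaled$hub_total <- system$hub_total * f
    st <- solve_competitive(scaled)
    data.frame(fold = f, species = names(st$free),
               role = c("hub", rep("partner", length(st$complex))),
               total = unname(st$totals), free = unname(st$free),
               fraction_bound = unname(st$fraction_bound),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert protein copies per cell to molar concentration
#'
#' @param copies copy number per cell, `>= 0`.
#' @param cell_volume cell volume in litres, `> 0`. The default
#'   1.66e-15 L corresponds to an E. coli cytoplasm for which 50
#'   copies/cell is 5e-8 M.
#' @return concentration in mol/L.
#' @export
#' @examples
#' copies_to_molar(c(50, 200))
copies_to_molar <- function(copies, cell_volume = 1.66e-15) {
  check_numeric_vec(copies, "copies", lower = 0)
  check_number(cell_volume, "cell_volume", lower = 0, strict = TRUE)
  copies / (6.02214076e23 * cell_volume)
}

#' @rdname copies_to_molar
#' @param conc concentration in mol/L, `>= 0`.
#' @export
molar_to_copies <- function(conc, cell_volume = 1.66e-15) {
  check_numeric_vec(conc, "conc", lower = 0)
  check_number(cell_volume, "cell_volume", lower = 0, strict = TRUE)
  conc * 6.02214076e23 * cell_volume
}

#' Scan sequestration percentages across candidate dissociation constants
#'
#' Convenience sensitivity scan for the pairwise model: for each candidate
#' KD, reports the integer-rounded percentages of hub and partner bound at
#' basal hub abundance and the partner bound percentage at a fold
#' overexpression of the hub. Useful when a dissociation constant is only
#' known approximately (e.g. "low micromolar").
#'
#' @param hub_total,partner_total basal totals (mol/L).
#' @param kds candidate dissociation constants (mol/L).
#' @param fold hub overexpression factor for the third column.
#' @return data frame with columns `kd`, `pct_hub_bound_basal`,
#'   `pct_partner_bound_basal`, `pct_partner_bound_fold` (integer percent,
#'   half-up rounding) and their unrounded counterparts.
#' @export
kd_sensitivity_scan <- function(hub_total, partner_total, kds,
                                fold = 1000) {
  check_numeric_vec(kds, "kds", lower = 0, strict = TRUE)
  res <- lapply(kds, function(k) {
    basal <- solve_pairwise(hub_total, partner_total, k)
    over <- solve_pairwise(hub_total * fold, partner_total, k)
    data.frame(
      kd = k,
      pct_hub_bound_basal = round_half_up(100 * basal$fraction_bound[1L]),
      pct_partner_bound_basal = round_half_up(100 * basal$fraction_bound[2L]),
      pct_partner_bound_fold = round_half_up(100 * over$fraction_bound[2L]),
      hub_bound_basal = unname(basal$fraction_bound[1L]),
      partner_bound_basal = unname(basal$fraction_bound[2L]),
      partner_bound_fold = unname(over$fraction_bound[2L]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
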