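#' Limiting ionic mobility table
#'
#' Limiting molar conductivities at 25 degrees C (S cm^2 mol^-1, per mole of
#' ion, i.e. |z| times the equivalent conductivity) from standard
#' physical-chemistry tabulations, plus documented effective values for the
#' organic species common in patch-pipette internals.  `Gluconate` uses the
#' widely adopted relative mobility of 0.33 vs K+; `HEPES` is the anionic
#' form; `ATP` and `GTP` are treated as their Mg complexes (effective
#' valence -2) because millimolar free Mg2+ is present in the recipes that
#' contain them; `EGTA` is the doubly deprotonated/complexed form at
#' physiological pH.
#'
#' @return A data frame with columns `species`, `z` (signed integer valence)
#'   and `lambda` (S cm^2/mol).
#' @export
ion_mobility_table <- function() {
  data.frame(
    species = c("H", "K", "Na", "Li", "Cs", "NH4", "TEA", "Choline",
                "Mg", "Ca", "Ba", "Zn",
                "OH", "Cl", "Br", "F", "I", "NO3", "HCO3", "H2PO4",
                "Acetate", "Gluconate", "HEPES", "MES", "Isethionate",
                "MeSO3",
                "SO4", "HPO4", "EGTA", "ATP", "GTP"),
    z = c(1, 1, 1, 1, 1, 1, 1, 1,
          2, 2, 2, 2,
          -1, -1, -1, -1, -1, -1, -1, -1,
          -1, -1, -1, -1, -1,
          -1,
          -2, -2, -2, -2, -2),
    lambda = c(349.8, 73.5, 50.11, 38.66, 77.2, 73.5, 32.7, 38.7,
               106.12, 118.94, 127.2, 105.6,
               198.3, 76.35, 78.1, 55.4, 76.8, 71.42, 44.5, 36.0,
               40.9, 24.4, 22.05, 26.8, 26.5,
               48.8,
               160.0, 114.0, 48.0, 50.0, 50.0),
    stringsAsFactors = FALSE)
}

#' Define an electrolyte solution
#'
#' A `solution_spec` is a named vector of charged-species concentrations
#' (mM) with a temperature.  Electroneutrality is enforced to within 1% of
#' the total ionic charge; alternatively one species can be designated as
#' the balancing counter-ion (the titration base/acid of the recipe) and
#' its concentration is adjusted to exact neutrality.
#'
#' @param species Named numeric vector, concentrations in mM.  Names must
#'   appear in [ion_mobility_table()] or in `mobility_override`.
#' @param temperature_K Temperature in kelvin (default 298.15).
#' @param balance_ion Optional species name whose concentration is adjusted
#'   to reach exact electroneutrality (e.g. `"K"` for a KOH-titrated
#'   internal).
#' @param mobility_override Optional data frame with columns
#'   `species`, `z`, `lambda` adding to or replacing built-in entries.
#' @return An object of class `solution_spec`.
#' @export
solution_spec <- function(species, temperature_K = 298.15,
                          balance_ion = NULL, mobility_override = NULL) {
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("solution_spec: 'species' must be a named vector (mM)")
  if (any(species < 0)) stop("solution_spec: concentrations must be >= 0")
  tab <- ion_mobility_table()
  if (!is.null(mobility_override)) {
    keep <- !(tab$species %in% mobility_override$species)
    tab <- rbind(tab[keep, ], mobility_override[, c("species", "z", "lambda")])
  }
  missing <- setdiff(names(species), tab$species)
  if (length(missing))
    stop("solution_spec: species missing from the mobility table: ",
         paste(missing, collapse = ", "),
         " (supply 'mobility_override')")
  z <- tab$z[match(names(species), tab$species)]
  if (!is.null(balance_ion)) {
    if (!balance_ion %in% names(species))
      species[balance_ion] <- 0
    z <- tab$z[match(names(species), tab$species)]
    i <- which(names(species) == balance_ion)
    rest <- sum(z[-i] * species[-i])
    need <- -rest / z[i]
    if (need < 0)
      stop("solution_spec: balancing '", balance_ion,
           "' would need a negative concentration")
    species[i] <- need
  }
  net <- sum(z * species)
  tot <- sum(abs(z) * species)
  if (tot > 0 && abs(net) > 0.01 * tot)
    stop(sprintf(
      "solution_spec: electroneutrality violated (net %.3g vs total %.3g meq/L); use 'balance_ion'",
      net, tot))
  structure(list(species = species, z = z,
                 lambda = tab$lambda[match(names(species), tab$species)],
                 temperature_K = temperature_K),
            class = "solution_spec")
}

#' @export
print.solution_spec <- function(x, ...) {
  cat(sprintf("<solution_spec> %d species, T = %.2f K\n",
              length(x$species), x$temperature_K))
  print(data.frame(mM = round(x$species, 4), z = x$z, lambda = x$lambda))
  invisible(x)
}

#' Read a solution recipe from a YAML file
#'
#' Recipe files list charged species in mM under `species:`, with optional
#' `temperature_K` and `balance_ion` keys.  Two example recipes matching
#' [solution_whole_cell_internal()] and [solution_acsf()] ship under
#' `inst/extdata/`.
#'
#' @param path YAML file path.
#' @return A [solution_spec()].
#' @export
read_solution <- function(path) {
  y <- yaml::read_yaml(path)
  solution_spec(unlist(y$species),
                temperature_K = if (is.null(y$temperature_K)) 298.15 else y$temperature_K,
                balance_ion = y$balance_ion)
}

#' Built-in solution recipes
#'
#' `solution_whole_cell_internal()` encodes the K-gluconate whole-cell
#' pipette internal (135 K gluconate, 10 HEPES, 5 KCl, 5 MgCl2, 0.1 EGTA,
#' 0.075 CaCl2, 2 ATP, 0.4 GTP, titrated to pH 7.35 with KOH) and
#' `solution_acsf()` the bicarbonate-buffered recording aCSF (126 NaCl,
#' 2.5 KCl, 1.2 MgCl2, 2.4 CaCl2, 1.2 NaH2PO4, 21.4 NaHCO3; pH 7.4 under
#' carbogen).  Speciation is fixed at the recipe pH: HEPES (pKa 7.55)
#' contributes its anionic fraction only, phosphate is split across
#' H2PO4-/HPO42- at pKa2 = 7.20 (with the matching bicarbonate shift), and
#' ATP/GTP enter as Mg complexes with effective valence -2.  K+ is the
#' balancing ion of the internal (the KOH titration).
#'
#' @param temperature_K Temperature for the junction computation.
#' @return A [solution_spec()].
#' @export
solution_whole_cell_internal <- function(temperature_K = 298.15) {
  pH <- 7.35
  hepes_anion <- 10 / (1 + 10^(7.55 - pH))
  solution_spec(c(
    K = 0,                       # balanced below (135 + 5 + KOH titration)
    Mg = 5, Ca = 0.075,
    Gluconate = 135,
    Cl = 5 + 2 * 5 + 2 * 0.075, # KCl + MgCl2 + CaCl2
    HEPES = hepes_anion,
    EGTA = 0.1, ATP = 2, GTP = 0.4),
    temperature_K = temperature_K, balance_ion = "K")
}

#' @rdname solution_whole_cell_internal
#' @export
solution_acsf <- function(temperature_K = 298.15) {
  pH <- 7.4
  f_hpo4 <- 1 / (1 + 10^(7.20 - pH))       # fraction HPO4^2- at pH 7.4
  hpo4 <- 1.2 * f_hpo4
  h2po4 <- 1.2 - hpo4
  solution_spec(c(
    Na = 126 + 1.2 + 21.4,
    K = 2.5, Mg = 1.2, Ca = 2.4,
    Cl = 126 + 2.5 + 2 * 1.2 + 2 * 2.4,
    HCO3 = 21.4 - hpo4,          # HCO3- consumed by H2PO4- deprotonation
    H2PO4 = h2po4, HPO4 = hpo4),
    temperature_K = temperature_K)
}

#' Compute a liquid junction potential
#'
#' Computes the junction potential between a pipette and a bath solution,
#' sign convention pipette-minus-bath, so that the offline correction of a
#' recorded membrane potential is `V_corrected = V_measured + V_J`.
#'
#' Two methods are provided.  `"henderson"` evaluates the closed-form
#' Henderson equation (linear mixing profile).  `"nernst_planck"` relaxes
#' the full one-dimensional electrodiffusion system (Nernst-Planck fluxes
#' under the zero-current constraint) from a sharp interface to its
#' stationary free-diffusion profile and integrates the electric field
#' across the junction; it makes no linear-profile assumption.  The two
#' agree to well under 1 mV on ordinary patch-clamp junctions.
#'
#' @param pipette,bath [solution_spec()] objects.
#' @param method `"henderson"` or `"nernst_planck"`.
#' @param temperature_K Optional override; defaults to the pipette
#'   solution's temperature.
#' @return An object of class `junction_result` with elements `V_J_mV`,
#'   `method`, and `species` (the merged concentration table).
#' @examples
#' compute_ljp(solution_whole_cell_internal(), solution_acsf())
#' @export
compute_ljp <- function(pipette, bath,
                        method = c("henderson", "nernst_planck"),
                        temperature_K = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(pipette, "solution_spec"), inherits(bath, "solution_spec"))
  if (is.null(temperature_K)) temperature_K <- pipette$temperature_K
  m <- merge_solutions(pipette, bath)
  v <- switch(method,
              henderson = ljp_henderson(m$z, m$lambda, m$cP, m$cB, temperature_K),
              nernst_planck = ljp_np(m$z, m$lambda, m$cP, m$cB, temperature_K))
  structure(list(V_J_mV = v, method = method,
                 temperature_K = temperature_K,
                 species = data.frame(species = m$species, z = m$z,
                                      lambda = m$lambda, pipette_mM = m$cP,
                                      bath_mM = m$cB)),
            class = "junction_result")
}

#' @export
print.junction_result <- function(x, ...) {
  cat(sprintf("<junction_result> V_J (pipette - bath) = %.2f mV  [%s, %.2f K]\n",
              x$V_J_mV, x$method, x$temperature_K))
  invisible(x)
}

merge_solutions <- function(pipette, bath) {
  sp <- union(names(pipette$species), names(bath$species))
  zP <- setNames(pipette$z, names(pipette$species))
  zB <- setNames(bath$z, names(bath$species))
  lP <- setNames(pipette$lambda, names(pipette$species))
  lB <- setNames(bath$lambda, names(bath$species))
  z <- ifelse(sp %in% names(zP), zP[sp], zB[sp])
  lam <- ifelse(sp %in% names(lP), lP[sp], lB[sp])
  cP <- ifelse(sp %in% names(pipette$species), pipette$species[sp], 0)
  cB <- ifelse(sp %in% names(bath$species), bath$species[sp], 0)
  list(species = sp, z = unname(z), lambda = unname(lam),
       cP = unname(cP), cB = unname(cB))
}

RT_over_F_mV <- function(T) 1000 * 8.314462618 * T / 96485.33212

ljp_henderson <- function(z, lam, cP, cB, T) {
  d <- cB - cP
  S1 <- sum(sign(z) * lam * d)
  S2 <- sum(abs(z) * lam * d)
  sumB <- sum(abs(z) * lam * cB)
  sumP <- sum(abs(z) * lam * cP)
  if (abs(S2) < 1e-12 || sumP <= 0 || sumB <= 0) return(0)
  # phi_bath - phi_pipette = -(RT/F) (S1/S2) ln(sumB/sumP); return pipette - bath
  RT_over_F_mV(T) * (S1 / S2) * log(sumB / sumP)
}

# Stationary free-diffusion junction: explicit relaxation of the NP system
# on [0,1] with a step initial condition at 0.5 and no-flux walls.  The
# junction potential of the spreading interface is time-invariant once a
# few grid cells wide, which the default t_end comfortably exceeds.
ljp_np <- function(z, lam, cP, cB, T, N = 201, t_end = 0.002) {
  if (all(abs(cP - cB) < 1e-12)) return(0)
  D <- (lam / abs(z))
  D <- D / max(D)
  x <- seq(0, 1, length.out = N)
  dx <- x[2] - x[1]
  C <- vapply(seq_along(z), function(i) ifelse(x < 0.5, cP[i], cB[i]),
              numeric(N))
  dt <- 0.2 * dx^2 / max(D)
  zD <- z * D
  z2D <- z^2 * D
  for (s in seq_len(ceiling(t_end / dt))) {
    dC <- (C[-1, , drop = FALSE] - C[-N, , drop = FALSE]) / dx
    Cm <- (C[-1, , drop = FALSE] + C[-N, , drop = FALSE]) / 2
    g <- -(dC %*% zD) / (Cm %*% z2D)       # d(phi F/RT)/dx at zero current
    J <- -sweep(dC, 2, D, "*") - (Cm * as.vector(g)) %*% diag(zD)
    J <- rbind(0, J, 0)
    C <- C - dt * (J[-1, , drop = FALSE] - J[-N, , drop = FALSE]) / dx
  }
  dC <- (C[-1, , drop = FALSE] - C[-N, , drop = FALSE]) / dx
  Cm <- (C[-1, , drop = FALSE] + C[-N, , drop = FALSE]) / 2
  g <- -(dC %*% zD) / (Cm %*% z2D)
  phiB_minus_phiP <- RT_over_F_mV(T) * sum(g) * dx
  -phiB_minus_phiP
}

#' Apply (or revert) the liquid-junction-potential correction
#'
#' Shifts every sample of an uncorrected voltage trace by `V_J`
#' (pipette-minus-bath), i.e. `V_corrected = V_measured + V_J`, and flips
#' the trace's `ljp_corrected` metadata flag.  With the published
#' whole-cell junction of -17.1 mV a nominal command of -54.9 mV becomes
#' the reported holding potential of -72.0 mV.  Attempting to correct an
#' already corrected trace is an error; passing `-V_J` to a corrected
#' trace reverts it exactly.
#'
#' @param x A voltage [trace()] whose `meta$ljp_corrected` is not `TRUE`.
#' @param V_J Junction potential in mV (pipette minus bath).
#' @return The corrected [trace()].
#' @export
apply_ljp_correction <- function(x, V_J) {
  stopifnot(inherits(x, "trace"))
  if (x$signal != "voltage")
    stop("apply_ljp_correction: only voltage traces are corrected")
  if (isTRUE(x$meta$ljp_corrected)) {
    # reverting with the opposite sign is allowed; re-correcting is not
    if (!is.null(x$meta$ljp_mV) && isTRUE(all.equal(-x$meta$ljp_mV, V_J))) {
      x$samples <- x$samples + V_J
      x$meta$ljp_corrected <- FALSE
      x$meta$ljp_mV <- NULL
      return(x)
    }
    stop("apply_ljp_correction: trace is already corrected (meta$ljp_corrected)")
  }
  x$samples <- x$samples + V_J
  if (V_J != 0) {
    x$meta$ljp_corrected <- TRUE
    x$meta$ljp_mV <- V_J
  }
  x
}
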