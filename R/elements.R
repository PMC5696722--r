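#' Elemental photon-interaction data
#'
#' The package ships a directory of plain-text elemental tables (one file per
#' element) with mass attenuation coefficients (mu/rho) and mass
#' energy-absorption coefficients (muen/rho) on a logarithmic 10-250 keV grid.
#' Coefficients for mixtures are obtained with the additivity (mixture) rule
#' and log-log interpolation in energy.
#'
#' @format Each table has fields `Z` (atomic number), `A` (g/mol), `energies`
#'   (keV), `mu_over_rho` and `muen_over_rho` (cm^2/g).
#' @name element-data
NULL

.element_dir <- function() {
  system.file("extdata", "elements", package = "kvseg", mustWork = TRUE)
}

.load_elements <- function() {
  if (!is.null(.kvseg_env$elements)) return(.kvseg_env$elements)
  files <- list.files(.element_dir(), pattern = "\\.txt$", full.names = TRUE)
  tabs <- list()
  for (f in files) {
    hdr <- readLines(f, n = 1L)
    m <- regmatches(hdr, regexec("element: (\\S+)\\s+Z: (\\d+)\\s+A: ([0-9.]+)", hdr))[[1]]
    d <- read.table(f, comment.char = "#")
    Z <- as.integer(m[3])
    stopifnot(all(diff(d[[1]]) > 0), all(d[[2]] > 0), all(d[[3]] > 0))
    tabs[[as.character(Z)]] <- list(
      symbol = m[2], Z = Z, A = as.numeric(m[4]),
      energies = d[[1]], mu_over_rho = d[[2]], muen_over_rho = d[[3]],
      pe = d[[4]], incoherent = d[[5]], coherent = d[[6]],
      log_e = log(d[[1]]), log_mu = log(d[[2]]), log_muen = log(d[[3]]),
      log_pe = log(d[[4]]), log_inc = log(d[[5]]), log_coh = log(d[[6]]))
  }
  .kvseg_env$elements <- tabs
  tabs
}

#' Look up an element by atomic number or symbol
#'
#' @param z Atomic number (integer) or element symbol (e.g. `"Ca"`).
#' @return A list with `symbol`, `Z`, `A` and the tabulated coefficient grids.
#' @export
element_table <- function(z) {
  tabs <- .load_elements()
  if (is.character(z)) {
    hit <- Filter(function(t) t$symbol == z, tabs)
    if (length(hit) == 0) stop("no elemental data for symbol '", z, "'")
    return(hit[[1]])
  }
  t <- tabs[[as.character(as.integer(z))]]
  if (is.null(t)) stop("no elemental data for Z = ", z)
  t
}

.element_symbol_to_z <- function(sym) {
  vapply(sym, function(s) element_table(s)$Z, integer(1))
}

#' Elemental mass coefficient at given energies
#'
#' Log-log interpolation of the shipped elemental grid. Energies outside the
#' tabulated 10-250 keV range are a hard error.
#'
#' @param z Atomic number or symbol.
#' @param energy Photon energies in keV.
#' @param kind `"attenuation"` (mu/rho) or `"energy_absorption"` (muen/rho).
#' @return Coefficients in cm^2/g, same length as `energy`.
#' @export
element_mass_coeff <- function(z, energy,
                               kind = c("attenuation", "energy_absorption")) {
  kind <- match.arg(kind)
  t <- element_table(z)
  rng <- range(t$energies)
  if (any(energy < rng[1] - 1e-9 | energy > rng[2] + 1e-9))
    stop("energy outside tabulated range [", rng[1], ", ", rng[2], "] keV")
  ly <- if (kind == "attenuation") t$log_mu else t$log_muen
  exp(approx(t$log_e, ly, xout = log(pmin(pmax(energy, rng[1]), rng[2])))$y)
}

# per-interaction components (photoelectric, incoherent, coherent) for an
# element, cm^2/g; log-log interpolated like element_mass_coeff
.element_components <- function(z, energy) {
  t <- element_table(z)
  le <- log(pmin(pmax(energy, min(t$energies)), max(t$energies)))
  list(pe = exp(approx(t$log_e, t$log_pe, xout = le)$y),
       incoherent = exp(approx(t$log_e, t$log_inc, xout = le)$y),
       coherent = exp(approx(t$log_e, t$log_coh, xout = le)$y))
}

# mixture-rule components for a material
.material_components <- function(material, energy) {
  pe <- inc <- coh <- numeric(length(energy))
  for (i in seq_along(material$Z)) {
    c_i <- .element_components(material$Z[i], energy)
    w <- material$composition[i]
    pe <- pe + w * c_i$pe; inc <- inc + w * c_i$incoherent
    coh <- coh + w * c_i$coherent
  }
  list(pe = pe, incoherent = inc, coherent = coh)
}

# mass coefficient of a fractional ("pseudo") element at non-integer Z:
# log-log interpolation in Z between the two neighbouring tabulated elements
.pseudo_element_coeff <- function(z, energy, kind = "attenuation") {
  tabs <- .load_elements()
  zs <- sort(vapply(tabs, `[[`, integer(1), "Z"))
  if (z < min(zs) || z > max(zs)) stop("pseudo-element Z outside data range")
  if (abs(z - round(z)) < 1e-9 && round(z) %in% zs)
    return(element_mass_coeff(round(z), energy, kind))
  lo <- max(zs[zs < z]); hi <- min(zs[zs > z])
  w <- (log(z) - log(lo)) / (log(hi) - log(lo))
  exp((1 - w) * log(element_mass_coeff(lo, energy, kind)) +
      w * log(element_mass_coeff(hi, energy, kind)))
}
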