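#' Define a material
#'
#' A material is a named medium with a mass density and an elemental
#' composition by mass fraction. Optionally it carries manufacturer/ICRU
#' reference values of relative electron density and effective atomic number,
#' used for dual-energy tissue assignment and for validation.
#'
#' Mass fractions must sum to 1 within 0.5% and are renormalized to exactly 1;
#' a larger deviation is rejected.
#'
#' @param name Material name.
#' @param mass_density Mass density in g/cm^3 (> 0).
#' @param composition Named numeric vector of mass fractions; names are
#'   element symbols (or atomic numbers).
#' @param ref_rho_e,ref_z_eff Optional reference relative electron density and
#'   effective atomic number.
#' @return An object of class `material`.
#' @examples
#' water <- material("Water", 1.0, c(H = 0.112, O = 0.888))
#' electrons_per_gram(water)
#' @export
material <- function(name, mass_density, composition,
                     ref_rho_e = NA_real_, ref_z_eff = NA_real_) {
  stopifnot(is.numeric(mass_density), mass_density > 0,
            is.numeric(composition), length(composition) > 0)
  s <- sum(composition)
  if (abs(s - 1) > 5e-3)
    stop("mass fractions of '", name, "' sum to ", signif(s, 5),
         ", outside [0.995, 1.005]")
  composition <- composition / s
  zs <- names(composition)
  if (is.null(zs)) stop("composition must be a named vector")
  Z <- if (all(grepl("^[0-9]+$", zs))) as.integer(zs) else .element_symbol_to_z(zs)
  A <- vapply(Z, function(z) element_table(z)$A, numeric(1))
  structure(list(name = name, mass_density = mass_density,
                 composition = unname(composition), Z = unname(Z), A = unname(A),
                 ref_rho_e = ref_rho_e, ref_z_eff = ref_z_eff),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, " rho =", x$mass_density, "g/cm3\n")
  cat("  ", paste0(vapply(x$Z, function(z) element_table(z)$symbol, ""),
                   ":", signif(100 * x$composition, 4), "%", collapse = " "), "\n")
  invisible(x)
}

#' Load the bundled material database
#'
#' Parses the shipped `materials.tsv` (tissue-substitute phantom plastics and
#' ICRU Report 44 tissues) and returns validated [material()] objects.
#'
#' @param group Optional filter: `"calibration"`, `"validation"` or `"mouse"`.
#' @param path Alternative database file in the same tab-separated format.
#' @return Named list of `material` objects.
#' @export
load_materials <- function(group = NULL, path = NULL) {
  if (is.null(path)) {
    if (is.null(.kvseg_env$materials)) {
      path <- system.file("extdata", "materials.tsv", package = "kvseg",
                          mustWork = TRUE)
      .kvseg_env$materials <- .parse_materials(path)
    }
    db <- .kvseg_env$materials
  } else db <- .parse_materials(path)
  if (!is.null(group)) {
    keep <- vapply(db, function(m) group %in% attr(m, "groups"), logical(1))
    db <- db[keep]
  }
  db
}

.parse_materials <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  check.names = FALSE, quote = "")
  out <- list()
  for (i in seq_len(nrow(d))) {
    parts <- strsplit(strsplit(d$composition[i], ";")[[1]], ":")
    w <- vapply(parts, function(p) as.numeric(p[2]), numeric(1)) / 100
    names(w) <- vapply(parts, `[[`, "", 1)
    m <- material(d$name[i], d$rho[i], w,
                  ref_rho_e = d$rho_e[i], ref_z_eff = d$z_eff[i])
    attr(m, "groups") <- strsplit(d$groups[i], ",")[[1]]
    out[[d$name[i]]] <- m
  }
  out
}

#' Electrons per gram of a material
#'
#' Sum over elements of w_i * Z_i / A_i, in mol of electrons per gram
#' (multiply by Avogadro's number for electrons per gram).
#'
#' @param material A [material()].
#' @return Mol electrons per gram.
#' @export
electrons_per_gram <- function(material) {
  stopifnot(inherits(material, "material"))
  sum(material$composition * material$Z / material$A)
}

#' Relative electron density
#'
#' Electron density (electrons per cm^3) relative to the reference medium,
#' by default liquid water at exactly 1.000 g/cm^3.
#'
#' @param material A [material()].
#' @param reference Reference material (default: water).
#' @return Dimensionless relative electron density.
#' @export
relative_electron_density <- function(material, reference = water_material()) {
  den <- reference$mass_density * electrons_per_gram(reference)
  if (den <= 0) stop("reference has no electrons")
  material$mass_density * electrons_per_gram(material) / den
}

#' Liquid water reference material
#' @return Water at 1.000 g/cm^3 (H 11.2%, O 88.8% by mass).
#' @export
water_material <- function() {
  if (is.null(.kvseg_env$water))
    .kvseg_env$water <- material("Water", 1.000, c(H = 0.112, O = 0.888),
                                 ref_rho_e = 1.000, ref_z_eff = 7.477)
  .kvseg_env$water
}

#' Effective atomic number
#'
#' Power-law effective atomic number: Zeff = (sum_i f_i Z_i^n)^(1/n), where
#' f_i is the electron fraction of element i. The default exponent n = 3.31
#' reproduces the manufacturer/ICRU reference values of all bundled materials
#' to better than 0.3%.
#'
#' @param material A [material()].
#' @param exponent Power-law exponent (> 0), default 3.31.
#' @return Dimensionless effective atomic number.
#' @export
effective_atomic_number <- function(material, exponent = 3.31) {
  stopifnot(inherits(material, "material"), exponent > 0)
  if (length(material$composition) == 0) stop("empty composition")
  el <- material$composition * material$Z / material$A
  f <- el / sum(el)
  sum(f * material$Z^exponent)^(1 / exponent)
}

#' Mass attenuation / energy-absorption coefficient of a material
#'
#' Mixture rule over the elemental tables with log-log interpolation in
#' energy.
#'
#' @param material A [material()].
#' @param energy Photon energies in keV (within the tabulated 10-250 keV).
#' @param kind `"attenuation"` or `"energy_absorption"`.
#' @return Coefficients in cm^2/g.
#' @export
mass_attenuation <- function(material, energy,
                             kind = c("attenuation", "energy_absorption")) {
  kind <- match.arg(kind)
  out <- numeric(length(energy))
  for (i in seq_along(material$Z))
    out <- out + material$composition[i] *
      element_mass_coeff(material$Z[i], energy, kind)
  out
}

#' Linear fit of mass density against relative electron density
#'
#' Ordinary least squares of rho (response) on rho_e (predictor) over a set
#' of materials; used to assign mass density from dual-energy electron
#' density maps.
#'
#' @param materials List of [material()] objects (>= 3) with reference rho_e
#'   (the reference value is used when present, otherwise computed).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
fit_rho_vs_rhoe <- function(materials) {
  stopifnot(length(materials) >= 3)
  rho <- vapply(materials, `[[`, numeric(1), "mass_density")
  rhoe <- vapply(materials, function(m)
    if (is.finite(m$ref_rho_e)) m$ref_rho_e else relative_electron_density(m),
    numeric(1))
  if (diff(range(rhoe)) < 1e-12) stop("degenerate fit: all rho_e equal")
  f <- lm(rho ~ rhoe)
  r2 <- 1 - sum(f$residuals^2) / sum((rho - mean(rho))^2)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r_squared = r2)
}
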