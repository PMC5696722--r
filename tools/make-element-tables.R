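# Regenerates inst/extdata/elements/*.txt — elemental mass attenuation and
# mass energy-absorption coefficient grids, 10-250 keV.
#
# Parameterized photon-interaction model (valid for the low-Z elements and
# the 10-250 keV range this package works in; all K-edges of the covered
# elements lie below 10 keV):
#   incoherent: Klein-Nishina on free electrons (exact closed form) x Z/A
#   photoelectric: C_pe * Z^4.166 / A / E^3.05, anchored to oxygen at 10 keV
#   coherent:   C_coh * Z^2.5  / A / E^1.75, anchored to oxygen at 10 keV
#   muen = photoelectric + incoherent * mean-electron-energy-fraction(KN)
# Run from the repository root: Rscript tools/make-element-tables.R

elements <- data.frame(
  symbol = c("H","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
             "Cl","Ar","K","Ca","Fe","Cu"),
  Z = c(1,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,26,29),
  A = c(1.008,9.012,10.811,12.011,14.007,15.999,18.998,20.180,22.990,24.305,
        26.982,28.086,30.974,32.06,35.45,39.948,39.098,40.078,55.845,63.546)
)

MEC2 <- 510.99895  # keV
TWO_PI_RE2 <- 4.98938e-25  # cm^2, 2*pi*r_e^2
N_A <- 6.02214076e23

kn_total <- function(E) {   # cm^2 per electron
  k <- E / MEC2
  TWO_PI_RE2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

# mean fraction of photon energy transferred to the Compton electron,
# from the Klein-Nishina differential cross section
kn_electron_fraction <- function(E) {
  k <- E / MEC2
  mu <- seq(-1, 1, length.out = 4001)
  vapply(k, function(kk) {
    eps <- 1 / (1 + kk * (1 - mu))           # E'/E
    dsig <- eps^2 * (eps + 1 / eps - (1 - mu^2))  # ~ dsigma/dOmega (unnorm)
    sum(dsig * (1 - eps)) / sum(dsig)
  }, numeric(1))
}

C_PE <- 15.78
C_COH <- 1.392

egrid <- exp(seq(log(10), log(250), length.out = 60))

dir.create("inst/extdata/elements", recursive = TRUE, showWarnings = FALSE)
fe <- kn_electron_fraction(egrid)
for (i in seq_len(nrow(elements))) {
  Z <- elements$Z[i]; A <- elements$A[i]; sym <- elements$symbol[i]
  incoh <- kn_total(egrid) * N_A * Z / A
  pe <- C_PE * Z^4.166 / A / egrid^3.05
  coh <- C_COH * Z^2.5 / A / egrid^1.75
  mu <- pe + incoh + coh
  muen <- pe + incoh * fe
  con <- file(sprintf("inst/extdata/elements/%02d_%s.txt", Z, sym), "w")
  writeLines(c(sprintf("# element: %s  Z: %d  A: %.4f", sym, Z, A),
               paste("# columns: energy_keV mu_over_rho_cm2g",
                     "muen_over_rho_cm2g pe_cm2g incoherent_cm2g",
                     "coherent_cm2g")), con)
  write.table(data.frame(sprintf("%.4f", egrid), sprintf("%.6e", mu),
                         sprintf("%.6e", muen), sprintf("%.6e", pe),
                         sprintf("%.6e", incoh), sprintf("%.6e", coh)),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
}
cat("wrote", nrow(elements), "element tables\n")
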