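#' Raw Miyazawa-Jernigan residue contact energies
#'
#' The standard 20x20 knowledge-based contact-energy table (Miyazawa & Jernigan
#' 1996, Table 3 upper half, units of RT), symmetrised.  Its most attractive
#' entry is the Leu-Leu pair at -7.37.  This table is the raw input to
#' [build_hydrophobic_matrix()], which maps it to dimensionless hydrophobic
#' strengths in \[0, 1\].
#'
#' @return a symmetric 20x20 numeric matrix with one-letter amino-acid
#'   dimnames.
#' @export
mj_raw_table <- function() {
  aa <- c("C","M","F","I","L","V","W","Y","A","G",
          "T","S","N","Q","D","E","H","R","K","P")
  up <- c(
    # C
    -5.44,-4.99,-5.80,-5.50,-5.83,-4.96,-4.95,-4.16,-3.57,-3.16,
    -3.11,-2.86,-2.59,-2.85,-2.41,-2.27,-3.60,-2.57,-1.95,-3.07,
    # M
    -5.46,-6.56,-6.02,-6.41,-5.32,-5.55,-4.91,-3.94,-3.39,
    -3.51,-3.03,-2.95,-3.30,-2.57,-2.89,-3.98,-3.12,-2.48,-3.45,
    # F
    -7.26,-6.84,-7.28,-6.29,-6.16,-5.66,-4.81,-4.13,
    -4.28,-4.02,-3.75,-4.10,-3.48,-3.56,-4.77,-3.98,-3.36,-4.25,
    # I
    -6.54,-7.04,-6.05,-5.78,-5.25,-4.58,-3.78,
    -4.03,-3.52,-3.24,-3.67,-3.17,-3.27,-4.14,-3.63,-3.01,-3.76,
    # L
    -7.37,-6.48,-6.14,-5.67,-4.91,-4.16,
    -4.34,-3.92,-3.74,-4.04,-3.40,-3.59,-4.54,-4.03,-3.37,-4.20,
    # V
    -5.52,-5.18,-4.62,-4.04,-3.38,
    -3.46,-3.05,-2.83,-3.07,-2.48,-2.67,-3.58,-3.07,-2.49,-3.32,
    # W
    -5.06,-4.66,-3.82,-3.42,
    -3.22,-2.99,-3.07,-3.11,-2.84,-2.99,-3.98,-3.41,-2.69,-3.73,
    # Y
    -4.17,-3.36,-3.01,
    -3.01,-2.78,-2.76,-2.97,-2.76,-2.79,-3.52,-3.16,-2.60,-3.19,
    # A
    -2.72,-2.31,
    -2.32,-2.01,-1.84,-1.89,-1.70,-1.51,-2.41,-1.83,-1.31,-2.03,
    # G
    -2.24,
    -2.08,-1.82,-1.74,-1.66,-1.59,-1.22,-2.15,-1.72,-1.15,-1.87,
    # T
    -2.12,-1.96,-1.88,-1.90,-1.80,-1.74,-2.42,-1.90,-1.31,-1.90,
    # S
    -1.67,-1.58,-1.49,-1.63,-1.48,-2.11,-1.62,-1.05,-1.57,
    # N
    -1.68,-1.71,-1.68,-1.51,-2.08,-1.64,-1.21,-1.53,
    # Q
    -1.54,-1.46,-1.42,-1.98,-1.80,-1.29,-1.73,
    # D
    -1.21,-1.02,-2.32,-2.29,-1.68,-1.33,
    # E
    -0.91,-2.15,-2.27,-1.80,-1.26,
    # H
    -3.05,-2.16,-1.35,-2.25,
    # R
    -1.55,-0.59,-1.70,
    # K
    -0.12,-0.97,
    # P
    -1.75)
  m <- matrix(NA_real_, 20, 20, dimnames = list(aa, aa))
  k <- 1L
  for (i in 1:20) for (j in i:20) {
    m[i, j] <- up[k]; m[j, i] <- up[k]; k <- k + 1L
  }
  m
}

#' Build the normalised hydrophobic interaction matrix
#'
#' Maps raw contact energies `e_ij` to dimensionless hydrophobic strengths
#' `eps_ij = (ebar + alpha * (e_ij - ebar)) / (2 * ebar)`, clamped to
#' \[0, 1\].  With the default `alpha = 1` ("sequence-flavoured") this reduces
#' to `e_ij / (2 * ebar)`; entries whose transform is negative (i.e. raw
#' `e_ij >= 0` with negative `ebar`) are set to zero so that electrostatics,
#' modelled separately, is not double counted.
#'
#' @param raw symmetric 20x20 raw contact-energy table (default
#'   [mj_raw_table()]).
#' @param alpha heterogeneity exponent (default 1, sequence-flavoured model).
#' @param ebar mean contact-energy scale used for normalisation (default
#'   -3.7; the most attractive raw entry, -7.37, is then mapped close to 1).
#' @return an object of class `hp_matrix`: list with `eps` (20x20 in \[0,1\]),
#'   `raw`, `ebar`, `alpha`.
#' @export
build_hydrophobic_matrix <- function(raw = mj_raw_table(), alpha = 1,
                                     ebar = -3.7) {
  if (!isTRUE(all.equal(raw, t(raw)))) stop("raw table must be symmetric")
  if (ebar == 0) stop("ebar must be non-zero")
  eps <- (ebar + alpha * (raw - ebar)) / (2 * ebar)
  eps[eps < 0] <- 0
  eps[eps > 1] <- 1
  structure(list(eps = eps, raw = raw, ebar = ebar, alpha = alpha),
            class = "hp_matrix")
}

#' @export
print.hp_matrix <- function(x, ...) {
  cat("Hydrophobic strength matrix: 20x20, range [",
      round(min(x$eps), 3), ",", round(max(x$eps), 3),
      "], ebar =", x$ebar, ", alpha =", x$alpha, "\n")
  invisible(x)
}
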