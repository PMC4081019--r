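#' State-classification cutoffs
#'
#' Distance cutoffs separating the conformational states of a diUb chain.
#' The open state is defined on the centre-of-mass distance; closed and the
#' compact substates on the hydrophobic patch-centre distances, using the
#' transition-state positions of the corresponding free-energy profiles:
#' 0.86 nm for I44-I44 (closed), 0.96 nm for I36-I36 and 0.93 nm for I36-I44.
#'
#' @param open d_com cutoff for the open state, nm.
#' @param closed d_I44I44 cutoff, nm.
#' @param i36i36 d_I36I36 cutoff, nm.
#' @param i36i44 d_I36I44 cutoff, nm.
#' @return list of class `state_cutoffs`.
#' @export
state_cutoffs <- function(open = 3.2, closed = 0.86, i36i36 = 0.96,
                          i36i44 = 0.93) {
  stopifnot(open > 0, closed > 0, i36i36 > 0, i36i44 > 0)
  structure(list(open = open, closed = closed, i36i36 = i36i36,
                 i36i44 = i36i44), class = "state_cutoffs")
}

#' Classify frames into conformational states
#'
#' Mutually exclusive classification with fixed precedence: a frame is
#' `open` if `d_com >= open cutoff`; otherwise `closed` if
#' `d_I44I44 <= closed cutoff`; otherwise `I36-I36` if `d_I36I36` is within
#' its cutoff while the other two interfaces are unformed; otherwise
#' `I36-I44` if `d_I36I44` is within its cutoff while I44-I44 is unformed;
#' otherwise `other-compact`.  Every frame receives exactly one label.
#'
#' @param op data frame of order parameters ([compute_order_params()]) with
#'   columns `d_com`, `d_I44I44`, `d_I36I36`, `d_I36I44`.
#' @param cutoffs a `state_cutoffs`.
#' @return factor of labels with levels `open`, `closed`, `I36-I36`,
#'   `I36-I44`, `other-compact`.
#' @export
classify_frame <- function(op, cutoffs = state_cutoffs()) {
  need <- c("d_com", "d_I44I44", "d_I36I36", "d_I36I44")
  miss <- setdiff(need, names(op))
  if (length(miss)) stop("missing order parameters: ",
                         paste(miss, collapse = ", "))
  lab <- rep("other-compact", nrow(op))
  closed <- op$d_I44I44 <= cutoffs$closed
  i3636 <- op$d_I36I36 <= cutoffs$i36i36
  i3644 <- op$d_I36I44 <= cutoffs$i36i44
  lab[i3644 & !closed] <- "I36-I44"
  lab[i3636 & !closed & !i3644] <- "I36-I36"
  lab[closed] <- "closed"
  lab[op$d_com >= cutoffs$open] <- "open"
  factor(lab, levels = c("open", "closed", "I36-I36", "I36-I44",
                         "other-compact"))
}

#' State populations with replicate standard deviations
#'
#' Per-replica state fractions are averaged and their standard deviation
#' across replicas reported, in percent.  Open + closed + compact sums to 100
#' and the three compact sub-fractions sum to the compact fraction.
#'
#' @param ops a data frame of order parameters, or a list of them (one per
#'   replica).
#' @param cutoffs a `state_cutoffs`.
#' @return object of class `state_populations`: list with `mean` and `sd`
#'   (named percent vectors over open/closed/compact/I36-I36/I36-I44/other),
#'   `per_replica` (matrix) and `replicas`.
#' @export
state_populations <- function(ops, cutoffs = state_cutoffs()) {
  if (is.data.frame(ops)) ops <- list(ops)
  if (length(ops) == 0L || any(!vapply(ops, nrow, 0L)))
    stop("empty trajectory")
  states <- c("open", "closed", "compact", "I36-I36", "I36-I44", "other")
  per <- t(vapply(ops, function(op) {
    lab <- classify_frame(op, cutoffs)
    p <- prop.table(table(lab)) * 100
    compact <- sum(p[c("I36-I36", "I36-I44", "other-compact")])
    c(open = unname(p["open"]), closed = unname(p["closed"]),
      compact = compact,
      `I36-I36` = unname(p["I36-I36"]), `I36-I44` = unname(p["I36-I44"]),
      other = unname(p["other-compact"]))
  }, numeric(6)))
  colnames(per) <- states
  structure(list(mean = colMeans(per),
                 sd = apply(per, 2, sd),
                 per_replica = per,
                 replicas = length(ops)),
            class = "state_populations")
}

#' @export
print.state_populations <- function(x, digits = 1, ...) {
  cat("State populations (%), mean (SD) over", x$replicas, "replicas:\n")
  for (s in names(x$mean)) {
    cat(sprintf("  %-13s %6.*f (%.*f)\n", s, digits, x$mean[s],
                digits, if (x$replicas > 1) x$sd[s] else 0))
  }
  invisible(x)
}

#' Write a populations table (Table-1 style) as TSV
#'
#' One row per model with mean interfacial energies and state populations
#' (percent, SDs in parentheses columns).
#'
#' @param rows named list: each element a list with `populations`
#'   (`state_populations`), `E_elec`, `E_HP` (means) and their SDs.
#' @param file output path.
#' @export
write_populations_tsv <- function(rows, file) {
  df <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    p <- r$populations
    data.frame(model = nm,
               E_elec = r$E_elec, E_elec_sd = r$E_elec_sd,
               E_HP = r$E_HP, E_HP_sd = r$E_HP_sd,
               open = p$mean["open"], open_sd = p$sd["open"],
               closed = p$mean["closed"], closed_sd = p$sd["closed"],
               compact = p$mean["compact"], compact_sd = p$sd["compact"],
               I36I36 = p$mean["I36-I36"], I36I36_sd = p$sd["I36-I36"],
               I36I44 = p$mean["I36-I44"], I36I44_sd = p$sd["I36-I44"],
               other = p$mean["other"], other_sd = p$sd["other"])
  }))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Entropy-enthalpy decomposition along an order parameter
#'
#' Bins the order parameter, computes `F(x) = -kT ln P(x)` and
#' `H(x) = <E | x>` per bin, and defines `TS(x) = H(x) - F(x)` so the identity
#' `F = H - TS` holds bin-wise by construction.  Correlation coefficients of
#' `TS` and `H` with `F` across the populated bins diagnose whether the
#' landscape along `x` is entropy- or enthalpy-dominated.
#'
#' @param x order-parameter series.
#' @param E potential-energy series (same length).
#' @param bins number of equal-width bins (default 50).
#' @param kT thermal energy.
#' @param min_count bins with fewer samples are excluded from the correlations
#'   (default 10).
#' @return object of class `thermo_profile`: data frame `profile` (bin centre,
#'   count, F, H, TS) plus `rho_SF`, `rho_HF`.
#' @export
entropy_enthalpy <- function(x, E, bins = 50, kT = 1, min_count = 10) {
  if (length(x) != length(E) || length(x) == 0L)
    stop("x and E must be equal-length, non-empty series")
  r <- range(x)
  if (diff(r) == 0) r <- r + c(-0.5, 0.5)
  br <- seq(r[1] - 1e-9, r[2] + 1e-9, length.out = bins + 1)
  ix <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  cnt <- tabulate(ix, nbins = bins)
  P <- cnt / sum(cnt)
  Fx <- -kT * log(P)
  Fx[!is.finite(Fx)] <- NA
  Fx <- Fx - min(Fx, na.rm = TRUE)
  Hx <- rep(NA_real_, bins)
  agg <- tapply(E, factor(ix, seq_len(bins)), mean)
  Hx[as.integer(names(agg))] <- agg
  # report enthalpy relative to its populated-bin minimum-F reference so the
  # profiles share an origin; a constant shift leaves TS - F correlations
  # untouched
  ref <- which.min(Fx)
  Hx <- Hx - Hx[ref]
  TSx <- Hx - Fx
  ok <- !is.na(Fx) & !is.na(Hx) & cnt >= min_count
  if (sum(ok) < 3L)
    warning("fewer than 3 populated bins; correlations unreliable")
  rho_SF <- if (sum(ok) >= 3L) cor(TSx[ok], Fx[ok]) else NA_real_
  rho_HF <- if (sum(ok) >= 3L) cor(Hx[ok], Fx[ok]) else NA_real_
  centers <- (head(br, -1) + tail(br, -1)) / 2
  structure(list(profile = data.frame(x = centers, count = cnt,
                                      F = Fx, H = Hx, TS = TSx,
                                      used = ok),
                 rho_SF = rho_SF, rho_HF = rho_HF, kT = kT),
            class = "thermo_profile")
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat("Entropy-enthalpy decomposition:",
      sum(x$profile$used), "populated bins;",
      "rho_SF =", round(x$rho_SF, 3), ", rho_HF =", round(x$rho_HF, 3), "\n")
  invisible(x)
}

#' Dissociation constant from a bound fraction
#'
#' Two-particle convention for a single dimer-forming pair in volume `V`:
#' with bound probability `P_b`, the free concentrations are
#' `[A] = [B] = (1 - P_b) / (N_A V)` and `[AB] = P_b / (N_A V)`, giving
#' `Kd = (1 - P_b)^2 / (P_b N_A V)`.  Finite-size definitions of Kd are
#' genuinely convention-dependent; the convention used is recorded in the
#' result.
#'
#' @param bound_fraction fraction of frames in a bound (non-open) state.
#' @param box_nm cubic box side in nm (alternative to `volume_L`).
#' @param volume_L box volume in litres.
#' @return list with `Kd` (mol/L), `convention`, and a `bound`/`unbound`
#'   one-sided flag when the fraction is 0 or 1.
#' @export
estimate_kd <- function(bound_fraction, box_nm = NULL, volume_L = NULL) {
  if (is.null(volume_L)) {
    if (is.null(box_nm)) stop("provide box_nm or volume_L")
    volume_L <- (box_nm^3) * 1e-24
  }
  NA_ <- 6.02214076e23
  conv <- "two-particle: Kd = (1-Pb)^2 / (Pb * NA * V)"
  if (bound_fraction <= 0) {
    return(list(Kd = Inf, lower_bound = 1 / (NA_ * volume_L),
                convention = conv,
                note = "no bound frames: Kd unbounded above"))
  }
  if (bound_fraction >= 1) {
    return(list(Kd = 0, upper_bound = 1 / (NA_ * volume_L),
                convention = conv,
                note = "fully bound: Kd below single-event resolution"))
  }
  kd <- (1 - bound_fraction)^2 / (bound_fraction * NA_ * volume_L)
  list(Kd = kd, convention = conv)
}

#' Apparent two-state readouts of a three-state system
#'
#' Experimental two-state analyses reference either the closed or the open
#' state.  A closed-referenced scheme reports everything that is not closed as
#' apparent open; an open-referenced scheme reports everything that is not
#' open as apparent closed.  With a sizeable compact population both schemes
#' are simultaneously "right", which reconciles seemingly contradictory
#' equilibrium measurements.
#'
#' @param open,closed,compact true three-state fractions (sum to 1).
#' @return list with `apparent_open` (closed-referenced), `apparent_closed`
#'   (open-referenced) and the input vector.
#' @export
three_state_apparent <- function(open, closed, compact) {
  v <- c(open = open, closed = closed, compact = compact)
  if (any(v < 0)) stop("negative state fractions")
  if (abs(sum(v) - 1) > 1e-6) stop("fractions must sum to 1")
  list(apparent_open = 1 - closed,
       apparent_closed = 1 - open,
       true_states = v)
}

#' Loop-closure entropy of the linkage constraint
#'
#' Gaussian-chain estimate of the probability of forming a bond/contact
#' constraint of length `I` in a chain of `N` residues with persistence
#' length `b`, with `m` constraints already present treated as an effective
#' chain-length reduction `N_eff = N / (m + 1)`:
#' `P = (3 / (2 pi N_eff b^2))^(3/2) * (4 pi / 3) * I^3`, and
#' `dS = k_B ln P`.
#'
#' @param N residue count of the chain (152 for diUb).
#' @param b persistence length, Angstrom (default 3.8, one C-alpha step).
#' @param I constraint length, Angstrom (default 4.0).
#' @param m constraints already present (default 0).
#' @return list with `P` and `dS` (in k_B units; negative).
#' @export
loop_entropy <- function(N = 152, b = 3.8, I = 4.0, m = 0) {
  stopifnot(N > 0, b > 0, I > 0, m >= 0)
  n_eff <- N / (m + 1)
  P <- (3 / (2 * pi * n_eff * b^2))^(3 / 2) * (4 * pi / 3) * I^3
  list(P = P, dS = log(P))
}
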