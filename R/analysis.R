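#' Hydrophobic patch definitions
#'
#' The two surface patches that dominate ubiquitin interfaces: the I44 patch
#' (L8, I44, V70) and the I36 patch (L8, I36, L71, L73).  Patch centres are
#' unweighted centroids over all beads (backbone and sidechain) of the member
#' residues.
#'
#' @return named list of residue-index vectors.
#' @export
ub_patches <- function() list(I44 = c(8L, 44L, 70L), I36 = c(8L, 36L, 71L, 73L))

# shift monomer 2 of one frame to the periodic image nearest monomer 1's COM
.unwrap_frame <- function(xyz, mono, box) {
  if (box <= 0) return(xyz)
  c1 <- colMeans(xyz[mono == 1L, , drop = FALSE])
  c2 <- colMeans(xyz[mono == 2L, , drop = FALSE])
  shift <- box * round((c2 - c1) / box)
  xyz[mono == 2L, ] <- sweep(xyz[mono == 2L, , drop = FALSE], 2, shift)
  xyz
}

.patch_center <- function(xyz, beads, mono, members) {
  sel <- beads$mono == mono & beads$resno %in% members
  colMeans(xyz[sel, , drop = FALSE])
}

#' Per-frame order parameters
#'
#' For every frame: the centre-of-mass distance between the two units
#' (`d_com`, equal bead weights), the inter-unit patch-centre distances
#' `d_I44I44`, `d_I36I36` and the cross distance `d_I36I44` (minimum of the
#' two cross pairings), the distal-M1 to proximal-G76 backbone-bead distance
#' `d_M1G76`, and optionally RMSDs to reference structures.
#'
#' @param traj a `cg_trajectory` of a two-monomer system.
#' @param references optional named list of reference `bead_model`s (two
#'   monomers); RMSD is computed over backbone beads after optimal
#'   superposition and reported as `rmsd_<name>`.
#' @param patches patch definition list (default [ub_patches()]).
#' @return data frame with one row per frame.
#' @export
compute_order_params <- function(traj, references = NULL,
                                 patches = ub_patches()) {
  beads <- traj$beads
  if (length(unique(beads$mono)) != 2L)
    stop("order parameters require a two-monomer trajectory")
  pos <- traj$pos
  nf <- dim(pos)[3]
  mono <- beads$mono

  ref_sel <- NULL
  ref_xyz <- list()
  if (!is.null(references)) {
    sel <- which(beads$kind == "backbone")
    for (nm in names(references)) {
      rb <- references[[nm]]$beads
      rsel <- which(rb$kind == "backbone")
      if (length(rsel) != length(sel))
        stop("reference '", nm, "' backbone bead count (", length(rsel),
             ") does not match the trajectory (", length(sel), ")")
      ref_xyz[[nm]] <- as.matrix(rb[rsel, c("x", "y", "z")])
    }
    ref_sel <- sel
  }

  m1_bb <- which(mono == 1L & beads$resno == min(beads$resno[mono == 1L]) &
                   beads$kind == "backbone")[1]
  g76_bb <- which(mono == 2L & beads$resno == max(beads$resno[mono == 2L]) &
                    beads$kind == "backbone")[1]

  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- .unwrap_frame(pos[, , f], mono, traj$box)
    c1 <- colMeans(xyz[mono == 1L, , drop = FALSE])
    c2 <- colMeans(xyz[mono == 2L, , drop = FALSE])
    p44_1 <- .patch_center(xyz, beads, 1L, patches$I44)
    p44_2 <- .patch_center(xyz, beads, 2L, patches$I44)
    p36_1 <- .patch_center(xyz, beads, 1L, patches$I36)
    p36_2 <- .patch_center(xyz, beads, 2L, patches$I36)
    nd <- function(a, b) sqrt(sum((a - b)^2))
    row <- data.frame(
      frame = f,
      d_com = nd(c1, c2),
      d_I44I44 = nd(p44_1, p44_2),
      d_I36I36 = nd(p36_1, p36_2),
      d_I36I44 = min(nd(p36_1, p44_2), nd(p44_1, p36_2)),
      d_M1G76 = nd(xyz[m1_bb, ], xyz[g76_bb, ]))
    for (nm in names(ref_xyz)) {
      row[[paste0("rmsd_", nm)]] <-
        kabsch_rmsd(xyz[ref_sel, , drop = FALSE], ref_xyz[[nm]])
    }
    rows[[f]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(traj$time) && length(traj$time) == nf) out$time <- traj$time
  out
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares best-fit root-mean-square deviation between two matched
#' coordinate sets, minimised over rigid rotations and translations.
#'
#' @param xyz,ref `m x 3` coordinate matrices (nm) with matched rows.
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(xyz, ref) {
  if (!all(dim(xyz) == dim(ref))) stop("selection size mismatch")
  x <- sweep(xyz, 2, colMeans(xyz))
  y <- sweep(ref, 2, colMeans(ref))
  s <- svd(crossprod(x, y))
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((x %*% t(rot) - y)^2)))
}

#' Two-dimensional free-energy surface
#'
#' `F = -k_B T * ln P` over a 2D histogram, shifted so the minimum of the
#' populated bins is zero.  Empty bins are `NA` (flagged, never imputed).
#'
#' @param x,y equal-length order-parameter series.
#' @param bins number of bins per axis, or a list of two break vectors.
#' @param kT thermal energy (free energies are reported in units of `kT` when
#'   `kT = 1`).
#' @param names axis names.
#' @return object of class `fes`: list with `breaks_x`, `breaks_y`, `F`
#'   (matrix, `kT` units), `counts`, `axes`.
#' @export
fes_2d <- function(x, y, bins = 40, kT = 1, names = c("x", "y")) {
  if (length(x) == 0L || length(x) != length(y))
    stop("x and y must be equal-length, non-empty series")
  if (is.list(bins)) {
    bx <- bins[[1]]; by <- bins[[2]]
  } else {
    pad <- function(v) {
      r <- range(v)
      if (diff(r) == 0) r <- r + c(-0.5, 0.5)
      seq(r[1] - 1e-9, r[2] + 1e-9, length.out = bins + 1)
    }
    bx <- pad(x); by <- pad(y)
  }
  ix <- cut(x, bx, include.lowest = TRUE, labels = FALSE)
  iy <- cut(y, by, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(ix) & !is.na(iy)
  counts <- matrix(0L, length(bx) - 1, length(by) - 1)
  tab <- table(factor(ix[keep], seq_len(nrow(counts))),
               factor(iy[keep], seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  P <- counts / sum(counts)
  Fm <- -kT * log(P)
  Fm[!is.finite(Fm)] <- NA
  Fm <- Fm - min(Fm, na.rm = TRUE)
  structure(list(breaks_x = bx, breaks_y = by, F = Fm, counts = counts,
                 kT = kT, axes = names),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat("2D free-energy surface:", x$axes[1], "x", x$axes[2], ";",
      nrow(x$F), "x", ncol(x$F), "bins;",
      sum(x$counts), "samples; max F =",
      round(max(x$F, na.rm = TRUE), 2), "kT\n")
  invisible(x)
}

#' Write a free-energy surface as a TSV grid
#'
#' Long format: bin centres of both axes, free energy, occupancy count.
#'
#' @param fes a `fes` object.
#' @param file output path.
#' @export
write_fes_tsv <- function(fes, file) {
  cx <- (head(fes$breaks_x, -1) + tail(fes$breaks_x, -1)) / 2
  cy <- (head(fes$breaks_y, -1) + tail(fes$breaks_y, -1)) / 2
  df <- expand.grid(x = cx, y = cy)
  names(df) <- fes$axes
  df$free_energy <- as.vector(fes$F)
  df$count <- as.vector(fes$counts)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Interfacial contact profile
#'
#' For frames whose centre-of-mass separation is at most `d_com_max`, counts
#' inter-monomer bead pairs within `cutoff` and attributes them to the
#' residues of each unit.  Hot spots are residues with more than one average
#' interfacial contact.  The full residue-residue mean contact matrix is
#' retained.
#'
#' @param traj a two-monomer `cg_trajectory`.
#' @param cutoff bead-pair contact cutoff, nm (default 0.8, aligned with the
#'   optimal hydrophobic distance).
#' @param d_com_max frame filter on the centre-of-mass distance, nm.
#' @return object of class `contact_profile`: per-residue mean counts for the
#'   distal and proximal units, hot-spot residue lists, the residue-residue
#'   matrix and the number of frames used.
#' @export
interfacial_contact_profile <- function(traj, cutoff = 0.8, d_com_max = 3.2) {
  beads <- traj$beads
  nres <- max(beads$resno)
  res <- .count_inter_contacts_cpp(traj$pos, as.integer(beads$mono),
                                   as.integer(beads$resno), as.integer(nres),
                                   cutoff, traj$box, d_com_max)
  if (res$frames_used == 0L)
    warning("no frames pass the d_com filter; contact profile is empty")
  structure(list(
    distal = as.numeric(res$profile1),
    proximal = as.numeric(res$profile2),
    matrix = res$matrix,
    residues = seq_len(nres),
    hot_spots_distal = which(res$profile1 > 1),
    hot_spots_proximal = which(res$profile2 > 1),
    frames_used = res$frames_used,
    cutoff = cutoff, d_com_max = d_com_max),
    class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("Interfacial contact profile over", x$frames_used, "frames",
      "(cutoff", x$cutoff, "nm, d_com <=", x$d_com_max, "nm)\n")
  cat("  hot spots distal:  ",
      paste(x$hot_spots_distal, collapse = " "), "\n")
  cat("  hot spots proximal:",
      paste(x$hot_spots_proximal, collapse = " "), "\n")
  invisible(x)
}

#' Interfacial symmetry score
#'
#' Pearson correlation between the per-residue interfacial contact profiles of
#' the distal and proximal units: 1 for perfectly symmetric interfaces, lower
#' when the covalent linkage breaks the symmetry.
#'
#' @param distal,proximal equal-length per-residue profiles, or a
#'   `contact_profile` as the first argument.
#' @return correlation in \[-1, 1\], or NA (with a warning) when a profile has
#'   zero variance.
#' @export
symmetry_score <- function(distal, proximal = NULL) {
  if (inherits(distal, "contact_profile")) {
    proximal <- distal$proximal; distal <- distal$distal
  }
  if (length(distal) != length(proximal)) stop("profiles must match in length")
  if (sd(distal) == 0 || sd(proximal) == 0) {
    warning("zero-variance contact profile; symmetry score undefined")
    return(NA_real_)
  }
  cor(distal, proximal)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto their mean structure (two alignment passes),
#' then the RMSF about the mean is reported per residue over the selected
#' beads.
#'
#' @param traj a `cg_trajectory`.
#' @param selection bead kinds to include (default backbone).
#' @return data frame with `resno`, `mono` and `rmsf` (nm).
#' @export
rmsf <- function(traj, selection = "backbone") {
  beads <- traj$beads
  sel <- which(beads$kind %in% selection)
  pos <- traj$pos
  nf <- dim(pos)[3]
  if (nf < 2L) stop("RMSF needs at least 2 frames")
  frames <- lapply(seq_len(nf), function(f)
    .unwrap_frame(pos[, , f], beads$mono, traj$box)[sel, , drop = FALSE])

  align_to <- function(frames, ref) lapply(frames, function(x) {
    xc <- sweep(x, 2, colMeans(x))
    yc <- sweep(ref, 2, colMeans(ref))
    s <- svd(crossprod(xc, yc))
    d <- sign(det(tcrossprod(s$v, s$u)))
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    xc %*% t(rot)
  })
  aligned <- align_to(frames, frames[[1]])
  for (pass in 1:2) {
    mean_xyz <- Reduce(`+`, aligned) / nf
    aligned <- align_to(aligned, mean_xyz)
  }
  mean_xyz <- Reduce(`+`, aligned) / nf
  dev2 <- Reduce(`+`, lapply(aligned, function(x)
    rowSums((x - mean_xyz)^2))) / nf
  data.frame(resno = beads$resno[sel], mono = beads$mono[sel],
             rmsf = sqrt(dev2))
}

#' Integrated autocorrelation time
#'
#' Sokal-windowed integrated autocorrelation time
#' `tau = 1 + 2 * sum(rho_k)`, summing while `k < window_factor * tau`.  The
#' ratio of the series length to `tau` is returned as a convergence index;
#' series shorter than `10 * tau` are flagged unreliable.
#'
#' @param series numeric series (assumed stationary).
#' @param window_factor Sokal window constant (default 5).
#' @return list with `tau` (frames), `n_eff_ratio` (length / tau) and
#'   `reliable`.
#' @export
autocorrelation_time <- function(series, window_factor = 5) {
  n <- length(series)
  if (n < 10L) stop("series too short for autocorrelation analysis")
  rho <- acf(series, lag.max = min(n - 1L, 5000L), plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
  tau <- 1
  for (k in 2:length(rho)) {
    tau <- tau + 2 * rho[k]
    if ((k - 1) >= window_factor * tau) break
  }
  tau <- max(tau, 1e-6)
  list(tau = tau, n_eff_ratio = n / tau, reliable = n >= 10 * tau)
}
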