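#' Detect native contacts from an all-atom monomer structure
#'
#' A residue pair (sequence separation >= `min_sep`) is in contact when any
#' pair of heavy atoms, one from each residue, lies within `cutoff` Angstrom.
#' Contacts are realised between the coarse-grained beads of the participating
#' atom groups: backbone group (N, CA, C, O, OXT) -> backbone bead, remaining
#' heavy atoms -> sidechain bead, so a residue pair can contribute up to four
#' bead contacts (CA-CA, CA-SC, SC-CA, SC-SC).  Each contact stores the native
#' distance between the corresponding beads, in nm.
#'
#' @param residues a `ub_residues` object.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param min_sep minimum residue sequence separation (default 3).
#' @return data frame with columns `res_i`, `res_j` (residue numbers, i < j),
#'   `kind_i`, `kind_j` ("backbone"/"sidechain"), `r_n` (nm), `eps` (1).
#' @export
detect_native_contacts <- function(residues, cutoff = 4.5, min_sep = 3) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (min_sep < 1) stop("min_sep must be >= 1")
  bb_names <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

  at <- do.call(rbind, lapply(residues, function(r) {
    a <- r$atoms
    data.frame(resno = r$resno,
               grp = ifelse(a$name %in% bb_names, "backbone", "sidechain"),
               gly = r$resname == "GLY",
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  }))
  # glycine has no sidechain bead; its rare non-backbone atoms map to backbone
  at$grp[at$gly] <- "backbone"

  xyz <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  sep_ok <- abs(at$resno[hit[, 1]] - at$resno[hit[, 2]]) >= min_sep
  hit <- hit[sep_ok, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(data.frame(res_i = integer(), res_j = integer(),
                      kind_i = character(), kind_j = character(),
                      r_n = numeric(), eps = numeric()))
  }
  a1 <- hit[, 1]; a2 <- hit[, 2]
  swap <- at$resno[a1] > at$resno[a2]
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  key <- paste(at$resno[a1], at$grp[a1], at$resno[a2], at$grp[a2], sep = "|")
  u <- !duplicated(key)
  out <- data.frame(res_i = at$resno[a1][u], res_j = at$resno[a2][u],
                    kind_i = at$grp[a1][u], kind_j = at$grp[a2][u],
                    stringsAsFactors = FALSE)
  out <- out[order(out$res_i, out$res_j, out$kind_i, out$kind_j), ]
  rownames(out) <- NULL

  # native CG bead distances
  model <- coarse_grain(residues)
  b <- model$beads
  bkey <- paste(b$resno, b$kind, sep = "|")
  i1 <- match(paste(out$res_i, out$kind_i, sep = "|"), bkey)
  i2 <- match(paste(out$res_j, out$kind_j, sep = "|"), bkey)
  dx <- b$x[i1] - b$x[i2]; dy <- b$y[i1] - b$y[i2]; dz <- b$z[i1] - b$z[i2]
  out$r_n <- sqrt(dx^2 + dy^2 + dz^2)
  out$eps <- 1
  out
}
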