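#' Parse a protein PDB file into residue records
#'
#' Reads a PDB file (via \pkg{bio3d}), keeps protein heavy atoms of the 20
#' standard amino acids, resolves alternate locations (highest occupancy wins,
#' ties broken by altloc letter so altloc "A" is retained by default) and
#' discards waters and heteroatoms.
#'
#' @param path path to a PDB file.
#' @param chain optional chain identifier(s) to keep (default: all).
#' @return an object of class `ub_residues`: a list of residue records, each a
#'   list with elements `chain`, `resno`, `resname` and `atoms` (a data frame
#'   with columns `name`, `x`, `y`, `z` in Angstrom and `occ`).
#' @export
parse_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% names(.aa3), , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  # heavy atoms only
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy))) {
    elesy <- sub("^[0-9]*", "", at$elety)
    elesy <- substr(elesy, 1, 1)
  }
  at <- at[toupper(trimws(elesy)) != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein residues in ", path)

  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution per (chain, residue, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  sel <- sort(ord[!duplicated(key[ord])])   # best altloc, file order restored
  at <- at[sel, , drop = FALSE]
  if (anyDuplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|")))
    stop("duplicate atom after altloc resolution")

  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  # preserve file order of residues
  rlev <- unique(rkey)
  res <- lapply(rlev, function(k) {
    rows <- at[rkey == k, , drop = FALSE]
    if (!all(is.finite(c(rows$x, rows$y, rows$z))))
      stop("non-finite coordinates in residue ", k)
    list(chain = rows$chain[1],
         resno = rows$resno[1],
         resname = rows$resid[1],
         atoms = data.frame(name = trimws(rows$elety),
                            x = rows$x, y = rows$y, z = rows$z,
                            occ = rows$o, stringsAsFactors = FALSE))
  })
  structure(res, class = "ub_residues", source = basename(path))
}

#' @export
print.ub_residues <- function(x, ...) {
  cat("Residue records:", length(x), "residues, chains:",
      paste(unique(vapply(x, `[[`, "", "chain")), collapse = ", "), "\n")
  invisible(x)
}

# one-letter sequence of a residue record list
residue_sequence <- function(residues) {
  unname(.aa3[vapply(residues, `[[`, "", "resname")])
}

#' Write a coarse-grained model as a PDB file
#'
#' Beads are written as pseudo-atoms: backbone beads as "CA", sidechain beads
#' as "CB".  Residue numbering is preserved (1-based); the distal unit is chain
#' A and the proximal unit chain B.  Positions are converted from nm to
#' Angstrom.
#'
#' @param model a `bead_model`.
#' @param file output path.
#' @param xyz optional `n x 3` coordinate matrix in nm overriding the model's
#'   own positions (e.g. one trajectory frame).
#' @return the path, invisibly.
#' @export
write_cg_pdb <- function(model, file, xyz = NULL) {
  b <- model$beads
  if (is.null(xyz)) xyz <- as.matrix(b[, c("x", "y", "z")])
  stopifnot(nrow(xyz) == nrow(b))
  xyz <- xyz * 10
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(xyz)),
                   resno = b$resno,
                   resid = .aa1to3[b$restype],
                   elety = ifelse(b$kind == "backbone", "CA", "CB"),
                   chain = ifelse(b$mono == 1L, "A", "B"),
                   o = rep(1, nrow(b)), b = rep(0, nrow(b)))
  invisible(file)
}

#' Coarse-grain an experimental dimer structure as an RMSD reference
#'
#' Maps a two-chain diUb PDB structure onto the two-bead representation and
#' labels the chain donating its C-terminal G76 tail to the linkage as distal,
#' the other as proximal.  The donor is identified as the chain whose last
#' backbone bead is closest to the acceptor site (Lys sidechain for isopeptide
#' linkages, M1 backbone for linear) of the partner chain.
#'
#' @param path path to a dimer PDB file.
#' @param linkage linkage type, one of "M1","K6","K11","K27","K29","K33",
#'   "K48","K63".
#' @param chains optional length-2 character vector naming the distal and
#'   proximal chains explicitly (fallback when auto-detection fails).
#' @return a two-monomer `bead_model` usable as an RMSD reference.
#' @export
map_reference_dimer <- function(path, linkage, chains = NULL) {
  linkage <- match.arg(linkage, setdiff(names(.linkage_sites), "free"))
  res <- parse_pdb(path)
  ch <- vapply(res, `[[`, "", "chain")
  uch <- unique(ch)
  if (length(uch) != 2L) {
    stop("reference dimer must have exactly 2 protein chains, found ",
         length(uch))
  }
  res_by <- lapply(uch, function(u) {
    r <- res[ch == u]
    structure(r, class = "ub_residues")
  })
  names(res_by) <- uch

  if (is.null(chains)) {
    site <- .linkage_sites[[linkage]]
    score <- function(donor, acceptor) {
      d <- donor[[length(donor)]]                       # C-terminal residue
      dn <- d$atoms[d$atoms$name %in% c("CA", "C"), , drop = FALSE]
      ares <- Filter(function(r) r$resno == site$resno, acceptor)
      if (length(ares) == 0L) return(NA_real_)
      a <- ares[[1]]$atoms
      if (site$kind == "sidechain") {
        a <- a[!a$name %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
        if (nrow(a) == 0L) a <- ares[[1]]$atoms
      } else {
        a <- a[a$name == "CA", , drop = FALSE]
      }
      min(sqrt(outer(dn$x, a$x, "-")^2 +
               outer(dn$y, a$y, "-")^2 +
               outer(dn$z, a$z, "-")^2))
    }
    s12 <- score(res_by[[1]], res_by[[2]])
    s21 <- score(res_by[[2]], res_by[[1]])
    if (all(is.na(c(s12, s21)))) {
      stop("cannot identify donor chain; supply `chains = c(distal, proximal)`")
    }
    distal <- if (isTRUE(s12 <= s21) || is.na(s21)) 1L else 2L
  } else {
    stopifnot(length(chains) == 2L, all(chains %in% uch))
    distal <- which(uch == chains[1])
  }
  proximal <- 3L - distal
  md <- coarse_grain(res_by[[distal]], monomer = "distal")
  mp <- coarse_grain(res_by[[proximal]], monomer = "proximal")
  combine_monomers(md, mp, source = basename(path))
}
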