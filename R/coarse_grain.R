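#' Coarse-grain residue records into a two-bead model
#'
#' Each residue is represented by a backbone bead at the C-alpha position and,
#' for non-glycine residues, a sidechain bead at the centre of mass of the
#' sidechain heavy atoms.  Positions are converted to nm.  Beads are ordered
#' by residue, backbone before sidechain.
#'
#' @param residues a `ub_residues` object from [parse_pdb()] (or a synthetic
#'   fixture).
#' @param monomer monomer label, "distal" or "proximal".
#' @return a `bead_model`: list with `beads` (data frame: `mono` 1 = distal /
#'   2 = proximal, `resno`, `kind`, `x`,`y`,`z` in nm, `mass`, `charge`,
#'   `restype`), `n_mono` and `source`.
#' @export
coarse_grain <- function(residues, monomer = c("distal", "proximal")) {
  monomer <- match.arg(monomer)
  mono_id <- if (monomer == "distal") 1L else 2L
  bb_names <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
  rows <- lapply(residues, function(r) {
    a <- r$atoms
    ca <- a[a$name == "CA", , drop = FALSE]
    if (nrow(ca) != 1L)
      stop("residue ", r$resno, " (", r$resname, ") is missing a CA atom")
    restype <- .aa3[[r$resname]]
    out <- data.frame(mono = mono_id, resno = r$resno, kind = "backbone",
                      x = ca$x / 10, y = ca$y / 10, z = ca$z / 10,
                      mass = 1, charge = 0, restype = restype,
                      stringsAsFactors = FALSE)
    if (r$resname != "GLY") {
      sc <- a[!a$name %in% bb_names, , drop = FALSE]
      if (nrow(sc) == 0L) {
        warning("residue ", r$resno, " (", r$resname,
                ") has no sidechain heavy atoms; backbone bead only")
      } else {
        com <- colMeans(sc[, c("x", "y", "z")])
        out <- rbind(out, data.frame(
          mono = mono_id, resno = r$resno, kind = "sidechain",
          x = com[1] / 10, y = com[2] / 10, z = com[3] / 10,
          mass = 1, charge = 0, restype = restype,
          stringsAsFactors = FALSE))
      }
    }
    out
  })
  beads <- do.call(rbind, rows)
  rownames(beads) <- NULL
  structure(list(beads = beads, n_mono = 1L,
                 source = attr(residues, "source") %||% "unknown"),
            class = "bead_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine two coarse-grained monomers into one dimer model
#'
#' @param distal,proximal `bead_model`s for the distal and proximal units.
#' @param source label recorded on the combined model.
#' @return a two-monomer `bead_model` (distal beads first, `mono = 1`).
#' @export
combine_monomers <- function(distal, proximal, source = "dimer") {
  bd <- distal$beads;  bd$mono <- 1L
  bp <- proximal$beads; bp$mono <- 2L
  beads <- rbind(bd, bp)
  rownames(beads) <- NULL
  structure(list(beads = beads, n_mono = 2L, source = source),
            class = "bead_model")
}

#' Assign charges at neutral pH
#'
#' Sidechain beads receive +1 for Lys/Arg, -1 for Asp/Glu and `q_his`
#' (default +0.5) for His; all backbone beads and termini are uncharged.
#'
#' @param model a `bead_model`.
#' @param q_his histidine sidechain charge (elementary charge units).
#' @return the model with its `charge` column populated.
#' @export
assign_charges <- function(model, q_his = 0.5) {
  b <- model$beads
  b$charge <- 0
  sc <- b$kind == "sidechain"
  b$charge[sc & b$restype %in% c("K", "R")] <- 1
  b$charge[sc & b$restype %in% c("D", "E")] <- -1
  b$charge[sc & b$restype == "H"] <- q_his
  model$beads <- b
  model
}

#' @export
print.bead_model <- function(x, ...) {
  b <- x$beads
  cat("Coarse-grained bead model (", x$source, "):\n", sep = "")
  cat("  monomers:", x$n_mono, " beads:", nrow(b),
      "(", sum(b$kind == "backbone"), "backbone /",
      sum(b$kind == "sidechain"), "sidechain )\n")
  cat("  net charge:", sum(b$charge), "\n")
  invisible(x)
}

# positions of a model as an n x 3 matrix (nm)
bead_xyz <- function(model) as.matrix(model$beads[, c("x", "y", "z")])

# row indices of a bead by monomer/residue/kind
bead_index <- function(model, mono, resno, kind) {
  b <- model$beads
  which(b$mono == mono & b$resno == resno & b$kind == kind)
}
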