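test_that("PDB round trip preserves residues, sequence and geometry", {
  f <- tempfile(fileext = ".pdb")
  fixture_to_pdb(ub_res, f)
  res <- parse_pdb(f)
  expect_length(res, 76L)
  expect_equal(vapply(res, `[[`, "", "resname"), ub_seq)
  expect_equal(res[[1]]$atoms$x, ub_res[[1]]$atoms$x, tolerance = 1e-3)
})

test_that("parse_pdb rejects empty input and resolves altlocs", {
  f <- tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(parse_pdb(f), "no protein residues")

  # altloc A (occ 0.6) and B (occ 0.4) for the CA of one residue
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CB  ALA A   1       1.500   1.400   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, f)
  res <- parse_pdb(f)
  ca <- res[[1]]$atoms[res[[1]]$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.0)  # higher occupancy / altloc A retained
})

test_that("coarse graining follows the two-bead rules", {
  m <- coarse_grain(ub_res)
  b <- m$beads
  n_gly <- sum(ub_seq == "GLY")
  expect_equal(nrow(b), 76 + 76 - n_gly)          # bead-count formula
  expect_equal(nrow(b), 146L)                     # ubiquitin sequence: 146
  # glycine: backbone bead only
  gly <- unique(b$resno[b$restype == "G"])
  expect_true(all(vapply(gly, function(r)
    sum(b$resno == r) == 1L, TRUE)))
  # deterministic ordering: residue-major, backbone before sidechain
  ord <- order(b$mono, b$resno, b$kind != "backbone")
  expect_equal(ord, seq_len(nrow(b)))
  # single-heavy-atom sidechain sits exactly on that atom
  ala <- mini$residues[[8]]
  expect_equal(ala$resname, "ALA")
  mm <- coarse_grain(mini$residues)
  sc <- mm$beads[mm$beads$resno == 8 & mm$beads$kind == "sidechain", ]
  cb <- ala$atoms[ala$atoms$name == "CB", ]
  expect_equal(c(sc$x, sc$y, sc$z), c(cb$x, cb$y, cb$z) / 10)
})

test_that("charges follow neutral-pH rules and are additive", {
  m <- assign_charges(coarse_grain(ub_res))
  b <- m$beads
  expect_true(all(b$charge[b$kind == "backbone"] == 0))
  expect_true(all(b$charge[b$kind == "sidechain" & b$restype == "K"] == 1))
  expect_true(all(b$charge[b$kind == "sidechain" & b$restype == "E"] == -1))
  expect_true(all(b$charge[b$kind == "sidechain" & b$restype == "H"] == 0.5))
  m2 <- assign_charges(coarse_grain(ub_res, "proximal"))
  dimer <- combine_monomers(m, m2)
  expect_equal(sum(dimer$beads$charge), 2 * sum(m$beads$charge))
})

test_that("native contacts match an exhaustive heavy-atom double loop", {
  res8 <- structure(ub_res[1:8], class = "ub_residues")
  got <- detect_native_contacts(res8, cutoff = 4.5, min_sep = 3)
  # independent brute-force oracle over atoms
  bb <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
  expected <- list()
  for (a in 1:7) for (b in (a + 1):8) {
    if (b - a < 3) next
    A <- res8[[a]]$atoms; B <- res8[[b]]$atoms
    ga <- ifelse(A$name %in% bb | res8[[a]]$resname == "GLY",
                 "backbone", "sidechain")
    gb <- ifelse(B$name %in% bb | res8[[b]]$resname == "GLY",
                 "backbone", "sidechain")
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                  (A$z[i] - B$z[j])^2)
      if (d <= 4.5)
        expected[[paste(a, ga[i], b, gb[j])]] <- TRUE
    }
  }
  expect_setequal(paste(got$res_i, got$kind_i, got$res_j, got$kind_j),
                  names(expected))
  # adjacent residues always excluded; canonical ordering, no duplicates
  full <- detect_native_contacts(ub_res)
  expect_true(all(full$res_j - full$res_i >= 3))
  expect_false(any(duplicated(
    paste(full$res_i, full$kind_i, full$res_j, full$kind_j))))
  expect_error(detect_native_contacts(ub_res, cutoff = -1), "cutoff")
})

test_that("hydrophobic matrix normalisation and clamping", {
  raw <- mj_raw_table()
  expect_equal(raw, t(raw))
  hp <- build_hydrophobic_matrix(raw)
  expect_true(all(hp$eps >= 0 & hp$eps <= 1))
  expect_equal(hp$eps, t(hp$eps))
  # a pair at exactly 2*ebar maps to 1
  raw2 <- raw; raw2["A", "A"] <- 2 * (-3.7)
  expect_equal(build_hydrophobic_matrix(raw2)$eps["A", "A"], 1)
  # raw >= 0 maps to 0 (electrostatics handled separately)
  raw2["G", "G"] <- 0.3; raw2["G", "T"] <- raw2["T", "G"] <- 0
  hp2 <- build_hydrophobic_matrix(raw2)
  expect_equal(hp2$eps["G", "G"], 0)
  expect_equal(hp2$eps["G", "T"], 0)
  # idempotent under re-application of the clamp
  eps <- hp$eps
  expect_true(all(pmax(0, pmin(1, eps)) == eps))
  expect_error(build_hydrophobic_matrix(raw, ebar = 0), "ebar")
  rawa <- raw; rawa[1, 2] <- rawa[1, 2] + 1
  expect_error(build_hydrophobic_matrix(rawa), "symmetric")
})

test_that("topology linkage bonds connect the named beads at stated lengths", {
  for (lk in setdiff(linkage_types(), "free")) {
    cg <- cg_model(ub_res, linkage = lk)
    link <- cg$topology$link
    b <- cg$model$beads
    expect_equal(b$mono[link$i], 1L)               # donor distal
    expect_equal(b$resno[link$i], 76L)             # G76
    expect_equal(b$kind[link$i], "backbone")
    expect_equal(b$mono[link$j], 2L)               # acceptor proximal
    if (lk == "M1") {
      expect_equal(b$resno[link$j], 1L)
      expect_equal(b$kind[link$j], "backbone")
      expect_equal(link$r0, 0.38)
    } else {
      expect_equal(b$resno[link$j], as.integer(sub("K", "", lk)))
      expect_equal(b$kind[link$j], "sidechain")
      expect_equal(b$restype[link$j], "K")
      expect_equal(link$r0, 0.40)
    }
    # linked pair excluded from non-bonded terms
    expect_true(any(cg$topology$exclusions$i == min(link$i, link$j) &
                      cg$topology$exclusions$j == max(link$i, link$j)))
  }
  free <- cg_model(ub_res, linkage = "free")
  expect_null(free$topology$link)
  b <- free$model$beads
  intra <- b$mono[free$topology$bonds$i] == b$mono[free$topology$bonds$j]
  expect_true(all(intra))                          # no inter-monomer bonded terms
  err <- tryCatch(cg_model(ub_res, linkage = "K99"), error = conditionMessage)
  for (v in linkage_types()) expect_match(err, v, fixed = TRUE)
})

test_that("every bonded pair is excluded and contacts are disjoint from bonds", {
  topo <- mini$topology
  exk <- paste(topo$exclusions$i, topo$exclusions$j)
  bk <- paste(pmin(topo$bonds$i, topo$bonds$j), pmax(topo$bonds$i, topo$bonds$j))
  expect_true(all(bk %in% exk))
  ck <- paste(pmin(topo$contacts$i, topo$contacts$j),
              pmax(topo$contacts$i, topo$contacts$j))
  expect_length(intersect(bk, ck), 0L)
})

test_that("topology serialisation round-trips losslessly", {
  cg <- cg_model(ub_res, linkage = "K48")
  f <- tempfile(fileext = ".json")
  topology_to_json(cg$topology, f)
  back <- topology_from_json(f)
  for (fld in c("bonds", "angles", "dihedrals", "contacts", "exclusions")) {
    expect_identical(dim(back[[fld]]), dim(cg$topology[[fld]]))
    for (cl in names(cg$topology[[fld]]))
      expect_identical(back[[fld]][[cl]], cg$topology[[fld]][[cl]],
                       label = paste(fld, cl))
  }
  expect_identical(back$link$r0, cg$topology$link$r0)
  expect_identical(back$link$k, cg$topology$link$k)
})

test_that("reference dimers are mapped with the donor chain labelled distal", {
  # synthetic closed-like dimer: chain A's G76 backbone placed next to chain
  # B's K48 sidechain
  resB <- lapply(ub_res, function(r) {
    r$chain <- "B"
    r$atoms$x <- r$atoms$x + 30
    r
  })
  resB <- structure(resB, class = "ub_residues", source = "synthetic_dimer")
  k48 <- resB[[48]]$atoms
  acceptor <- colMeans(k48[k48$name != "CA", c("x", "y", "z")])
  resA <- ub_res
  g76 <- resA[[76]]$atoms[resA[[76]]$atoms$name == "CA", c("x", "y", "z")]
  shift <- unlist(acceptor) - unlist(g76) - c(4, 0, 0)
  resA <- lapply(resA, function(r) {
    r$atoms$x <- r$atoms$x + shift[1]
    r$atoms$y <- r$atoms$y + shift[2]
    r$atoms$z <- r$atoms$z + shift[3]
    r
  })
  resA <- structure(resA, class = "ub_residues", source = "synthetic_dimer")
  f <- tempfile(fileext = ".pdb")
  fixture_to_pdb(c(resA, resB), f)
  ref <- map_reference_dimer(f, "K48")
  expect_equal(ref$n_mono, 2L)
  expect_equal(nrow(ref$beads), 292L)
  # distal unit (mono 1) must be chain A: its first backbone bead matches A's M1
  m1 <- ref$beads[ref$beads$mono == 1L & ref$beads$resno == 1L &
                    ref$beads$kind == "backbone", ]
  a1 <- resA[[1]]$atoms[resA[[1]]$atoms$name == "CA", ]
  expect_equal(m1$x * 10, a1$x, tolerance = 1e-2)
  # mapped reference vs itself: RMSD 0
  sel <- ref$beads$kind == "backbone"
  expect_equal(kabsch_rmsd(model_xyz(ref)[sel, ], model_xyz(ref)[sel, ]), 0,
               tolerance = 1e-10)
  expect_error(map_reference_dimer(f, "K99"))
})
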