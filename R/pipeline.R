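#' Default run configuration for the pipeline
#'
#' @param pdb monomer PDB path, or "synthetic" for the built-in
#'   ubiquitin-sequence surrogate ([make_ub_monomer()]).
#' @param linkage linkage type name.
#' @param out output directory.
#' @param steps,replicas,stride,temperature,concentration simulation settings
#'   (see [sim_config()]).
#' @param seed_base base replica seed.
#' @return nested configuration list (class `run_config`).
#' @export
run_config <- function(pdb = "synthetic", linkage = "free", out = "ubscape_out",
                       steps = 200000L, replicas = 4L, stride = 200L,
                       temperature = 50, concentration = 0.005,
                       seed_base = 1000L) {
  structure(list(
    model = list(pdb = pdb, linkage = linkage),
    simulate = list(steps = as.integer(steps), replicas = as.integer(replicas),
                    stride = as.integer(stride), temperature = temperature,
                    concentration = concentration,
                    seed_base = as.integer(seed_base)),
    analyze = list(cutoffs = unclass(state_cutoffs()), fes_bins = 40L),
    output = list(dir = out)), class = "run_config")
}

.load_monomer <- function(pdb) {
  if (identical(pdb, "synthetic")) make_ub_monomer() else parse_pdb(pdb)
}

#' Run the modelling/simulation/analysis pipeline
#'
#' Commands compose: `build` constructs the coarse-grained model and topology
#' and serialises them; `simulate` runs the replicas; `analyze` computes order
#' parameters, a free-energy surface and the interfacial contact profile;
#' `states` classifies frames and writes populations plus the three-state
#' reconciliation and a Kd estimate; `report` runs all of the above.
#'
#' @param config a `run_config` (or a list with the same shape, e.g. parsed
#'   from YAML).
#' @param command one of "build", "simulate", "analyze", "states", "report".
#' @param quiet suppress progress messages.
#' @return (invisibly) a list of produced artifact paths.
#' @export
run_pipeline <- function(config = run_config(), command = "report",
                         quiet = FALSE) {
  command <- match.arg(command,
                       c("build", "simulate", "analyze", "states", "report"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output$dir, f)
  artifacts <- list()

  if (command %in% c("build", "report") ||
      (command != "build" && !file.exists(out("model.rds")))) {
    t0 <- Sys.time()
    lk <- config$model$linkage
    if (!lk %in% linkage_types())
      stop("invalid linkage '", lk, "'; valid values are: ",
           paste(linkage_types(), collapse = ", "))
    residues <- .load_monomer(config$model$pdb)
    cg <- cg_model(residues, linkage = lk)
    saveRDS(cg, out("model.rds"))
    topology_to_json(cg$topology, out("topology.json"))
    write_cg_pdb(cg$model, out("model_cg.pdb"))
    say("build: %d beads, %d native contacts, linkage %s [%.1fs]",
        nrow(cg$model$beads), nrow(cg$topology$contacts), lk,
        as.numeric(Sys.time() - t0, units = "secs"))
    artifacts$model <- out("model.rds")
    if (command == "build") return(invisible(artifacts))
  }

  cg <- readRDS(out("model.rds"))
  sim <- config$simulate
  cfg <- sim_config(temperature = sim$temperature, steps = sim$steps,
                    replicas = sim$replicas, stride = sim$stride,
                    concentration = sim$concentration,
                    seed_base = sim$seed_base)

  if (command %in% c("simulate", "report") ||
      (command %in% c("analyze", "states") &&
         !file.exists(out("trajectories.rds")))) {
    t0 <- Sys.time()
    runs <- run_replicas(cg$model, cg$topology, cfg, cg$params)
    saveRDS(runs$trajectories, out("trajectories.rds"))
    jsonlite::write_json(runs$manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("simulate: %d replicas x %d steps (%d frames each) [%.1fs]",
        cfg$replicas, cfg$steps, cfg$steps %/% cfg$stride,
        as.numeric(Sys.time() - t0, units = "secs"))
    artifacts$trajectories <- out("trajectories.rds")
    if (command == "simulate") return(invisible(artifacts))
  }

  trajs <- readRDS(out("trajectories.rds"))
  t0 <- Sys.time()
  ops <- lapply(trajs, compute_order_params)
  ens <- lapply(trajs, trajectory_energies, model = cg$model,
                topology = cg$topology, params = cg$params)
  all_ops <- do.call(rbind, Map(function(o, r) { o$replica <- r; o },
                                ops, seq_along(ops)))
  all_en <- do.call(rbind, ens)
  write.table(cbind(all_ops, all_en[, c("E_elec", "E_HP", "E_total")]),
              out("order_params.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  kT <- cg$params$k_B * cfg$temperature
  fes <- fes_2d(all_ops$d_com, all_ops$d_I44I44,
                bins = config$analyze$fes_bins, kT = 1,
                names = c("d_com", "d_I44I44"))
  write_fes_tsv(fes, out("fes_dcom_dI44I44.tsv"))
  prof <- tryCatch({
    p <- merge_contact_profiles(lapply(trajs, interfacial_contact_profile))
    df <- data.frame(resno = p$residues, distal = p$distal,
                     proximal = p$proximal)
    write.table(df, out("contact_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    p
  }, warning = function(w) NULL)
  say("analyze: %d frames, %d order parameters [%.1fs]",
      nrow(all_ops), ncol(all_ops), as.numeric(Sys.time() - t0, units = "secs"))
  artifacts$order_params <- out("order_params.tsv")
  if (command == "analyze") return(invisible(artifacts))

  t0 <- Sys.time()
  cuts <- do.call(state_cutoffs, config$analyze$cutoffs)
  pops <- state_populations(ops, cuts)
  elec_mu <- vapply(ens, function(e) mean(e$E_elec), 0)
  hp_mu <- vapply(ens, function(e) mean(e$E_HP), 0)
  rows <- list()
  rows[[paste0("CG", config$model$linkage)]] <- list(
    populations = pops,
    E_elec = mean(elec_mu), E_elec_sd = sd(elec_mu),
    E_HP = mean(hp_mu), E_HP_sd = sd(hp_mu))
  write_populations_tsv(rows, out("populations.tsv"))

  frac <- pops$mean / 100
  app <- three_state_apparent(frac[["open"]], frac[["closed"]],
                              frac[["compact"]])
  kd <- estimate_kd(1 - frac[["open"]], box_nm = cfg$box)
  summary <- list(
    populations_pct = as.list(pops$mean), populations_sd = as.list(pops$sd),
    symmetry_score = if (!is.null(prof)) symmetry_score(prof) else NA,
    three_state = list(apparent_open = app$apparent_open,
                       apparent_closed = app$apparent_closed),
    Kd_M = kd$Kd, Kd_convention = kd$convention)
  jsonlite::write_json(summary, out("states_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("states: open %.1f%% closed %.1f%% compact %.1f%% [%.1fs]",
      pops$mean[["open"]], pops$mean[["closed"]], pops$mean[["compact"]],
      as.numeric(Sys.time() - t0, units = "secs"))
  artifacts$populations <- out("populations.tsv")
  artifacts$summary <- out("states_summary.json")
  invisible(artifacts)
}

#' Merge contact profiles across replicas
#'
#' Frame-weighted average of per-replica interfacial contact profiles.
#'
#' @param profiles list of `contact_profile`s.
#' @return a merged `contact_profile`.
#' @export
merge_contact_profiles <- function(profiles) {
  w <- vapply(profiles, `[[`, 0L, "frames_used")
  if (sum(w) == 0) {
    warning("no frames pass the d_com filter in any replica")
    p <- profiles[[1]]
    return(p)
  }
  wn <- w / sum(w)
  acc <- function(field) Reduce(`+`, Map(function(p, wi) p[[field]] * wi,
                                         profiles, wn))
  p <- profiles[[1]]
  p$distal <- acc("distal"); p$proximal <- acc("proximal")
  p$matrix <- acc("matrix")
  p$hot_spots_distal <- which(p$distal > 1)
  p$hot_spots_proximal <- which(p$proximal > 1)
  p$frames_used <- sum(w)
  p
}

#' Scan several linkage models under matched sampling
#'
#' Builds, simulates and summarises one model per requested linkage type with
#' identical sampling settings, returning the Table-1-style quantities per
#' model: state populations, mean interfacial energies and the interfacial
#' symmetry score.
#'
#' @param monomer a `ub_residues` monomer.
#' @param linkages character vector of linkage types (may include "free").
#' @param config `sim_config` shared by all models.
#' @param params `ff_params`.
#' @param cutoffs `state_cutoffs`.
#' @param quiet suppress progress messages.
#' @return named list per linkage: `populations` (`state_populations`),
#'   `E_elec`, `E_HP` (+ SDs), `symmetry`, `ops` (order parameters with
#'   replica column).
#' @export
linkage_scan <- function(monomer, linkages, config = sim_config(replicas = 3L),
                         params = ff_params(), cutoffs = state_cutoffs(),
                         quiet = FALSE) {
  out <- list()
  for (lk in linkages) {
    nm <- if (lk == "free") "free" else paste0("CG", lk)
    t0 <- Sys.time()
    cg <- cg_model(monomer, linkage = lk, params = params)
    runs <- run_replicas(cg$model, cg$topology, config, params)
    ops <- lapply(runs$trajectories, compute_order_params)
    ens <- lapply(runs$trajectories, trajectory_energies, model = cg$model,
                  topology = cg$topology, params = params)
    elec_mu <- vapply(ens, function(e) mean(e$E_elec), 0)
    hp_mu <- vapply(ens, function(e) mean(e$E_HP), 0)
    prof <- merge_contact_profiles(
      lapply(runs$trajectories, interfacial_contact_profile))
    sym <- suppressWarnings(symmetry_score(prof))
    all_ops <- do.call(rbind, Map(function(o, r) { o$replica <- r; o },
                                  ops, seq_along(ops)))
    out[[nm]] <- list(
      linkage = lk,
      populations = state_populations(ops, cutoffs),
      E_elec = mean(elec_mu), E_elec_sd = sd(elec_mu),
      E_HP = mean(hp_mu), E_HP_sd = sd(hp_mu),
      symmetry = sym, ops = all_ops)
    if (!quiet)
      message(sprintf("linkage %s: open %.1f%% [%.1fs]", lk,
                      out[[nm]]$populations$mean[["open"]],
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  out
}
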