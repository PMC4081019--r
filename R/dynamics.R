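# deterministic uniform/normal draws derived from an integer seed without
# touching the global R RNG state
.local_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.random_rotation <- function() {
  # uniform random rotation from a normalised quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Initial placement of a two-monomer system
#'
#' Monomer 1 keeps its native coordinates (centred); monomer 2 is rigidly
#' rotated at random and placed so the two units do not clash.  For a linked
#' model the rotation pivots about the acceptor bead, which is placed at the
#' linkage reference distance from the donor bead along the outward direction;
#' for the free model the units are separated by at least `gap` nm
#' surface-to-surface.  Placements are retried until the closest inter-monomer
#' bead pair exceeds `min_dist`.
#'
#' @param model two-monomer `bead_model`.
#' @param topology `cg_topology` (used for the linkage beads).
#' @param seed integer seed for the random orientation.
#' @param gap free-model surface-to-surface separation, nm.
#' @param min_dist minimal allowed inter-monomer bead distance, nm.
#' @param tries maximum placement attempts.
#' @return `n x 3` coordinate matrix in nm.
#' @export
place_dimer <- function(model, topology, seed = 1L, gap = 1.0,
                        min_dist = 0.34, tries = 400L) {
  stopifnot(model$n_mono == 2L)
  b <- model$beads
  xyz <- bead_xyz(model)
  i1 <- b$mono == 1L; i2 <- b$mono == 2L
  x1 <- sweep(xyz[i1, , drop = FALSE], 2, colMeans(xyz[i1, , drop = FALSE]))
  x2n <- sweep(xyz[i2, , drop = FALSE], 2, colMeans(xyz[i2, , drop = FALSE]))
  r1 <- max(sqrt(rowSums(x1^2)))
  r2 <- max(sqrt(rowSums(x2n^2)))

  link <- topology$link
  .local_rng(seed, function() {
    best <- NULL; best_d <- -Inf
    for (t in seq_len(tries)) {
      R2 <- .random_rotation()
      x2 <- x2n %*% t(R2)
      if (is.null(link)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        x2p <- sweep(x2, 2, (r1 + r2 + gap) * u, "+")
      } else {
        di <- which(which(i1) == link$i)
        ai <- which(which(i2) == link$j)
        donor <- x1[di, ]
        out_dir <- donor / max(sqrt(sum(donor^2)), 1e-6)
        target <- donor + link$r0 * out_dir
        x2p <- sweep(x2, 2, target - x2[ai, ], "+")
      }
      dmin <- min(sqrt(outer(rowSums(x1^2), rowSums(x2p^2), "+") -
                         2 * tcrossprod(x1, x2p)))
      if (dmin > best_d) { best_d <- dmin; best <- x2p }
      if (dmin >= min_dist) break
    }
    out <- xyz
    out[i1, ] <- x1
    out[i2, ] <- best
    out
  })
}

#' Langevin dynamics run
#'
#' BAOAB-splitting Langevin integrator at fixed reduced temperature with
#' friction `gamma = 1 / coupling_time`.  Inter-monomer non-bonded pairs use
#' the periodic minimum-image convention when the configuration defines a box.
#' Identical seed and inputs give bit-identical trajectories; a run can be
#' resumed exactly from the returned `final_state`.
#'
#' @param model,topology,params model objects.
#' @param config a `sim_config` (its `seeds[1]` is used unless `seed` given).
#' @param init optional initial `n x 3` coordinates (default: the model's
#'   coordinates for a monomer, [place_dimer()] for a dimer).
#' @param state optional `final_state` of a previous run to resume from
#'   (positions, velocities and RNG state are taken from it).
#' @param seed integer seed for velocities, placement and the thermostat.
#' @param steps,stride overrides of the configured step count / frame stride.
#' @return a `cg_trajectory`: list with `pos` (`n x 3 x F` array, nm), `time`,
#'   `epot`, `ekin`, `box`, `seed`, `beads` (bead metadata) and `final_state`.
#' @export
langevin_run <- function(model, topology, config = sim_config(),
                         params = ff_params(), init = NULL, state = NULL,
                         seed = NULL, steps = NULL, stride = NULL) {
  seed <- if (is.null(seed)) config$seeds[1] else as.integer(seed)
  steps <- if (is.null(steps)) config$steps else as.integer(steps)
  stride <- if (is.null(stride)) config$stride else as.integer(stride)
  box <- if (model$n_mono == 2L) config$box else 0
  spec <- .engine_spec(model, topology, params, box = box)
  n <- spec$n
  kT <- params$k_B * config$temperature

  if (!is.null(state)) {
    pos <- state$pos; vel <- state$vel; rng <- state$rng_state
  } else {
    pos <- if (!is.null(init)) init else if (model$n_mono == 2L)
      place_dimer(model, topology, seed = seed) else bead_xyz(model)
    vel <- .local_rng(seed, function()
      matrix(rnorm(3 * n, sd = sqrt(max(kT, 0) / config$mass)), n, 3))
    if (kT == 0) vel[] <- 0
    rng <- .rng_init_cpp(seed)
  }

  res <- .cg_langevin_cpp(spec, pos, vel, config$dt,
                          1 / config$coupling_time, kT, config$mass,
                          steps, stride, rng)
  if (isTRUE(res$diverged)) {
    stop("simulation diverged at step ", res$diverged_step,
         " (bead displacement exceeded half the box per step); ",
         "reduce the time step or check the starting structure")
  }
  structure(list(pos = res$frames, time = res$time, epot = res$epot,
                 ekin = res$ekin, box = box, seed = seed,
                 dt = config$dt, stride = stride,
                 beads = model$beads[, c("mono", "resno", "kind", "charge",
                                         "restype")],
                 final_state = list(pos = res$pos, vel = res$vel,
                                    rng_state = res$rng_state)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  f <- if (length(dim(x$pos)) == 3L) dim(x$pos)[3] else 0L
  cat("CG trajectory:", f, "frames,", nrow(x$beads), "beads, box =",
      round(x$box, 3), "nm, seed =", x$seed, "\n")
  invisible(x)
}

#' Kinetic temperature of a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param k_B Boltzmann constant in reduced units.
#' @return per-frame kinetic temperature estimates (from the saved kinetic
#'   energies; `2 Ekin / (3 N k_B)`).
#' @export
kinetic_temperature <- function(traj, k_B = UB_KB) {
  n <- nrow(traj$beads)
  2 * traj$ekin / (3 * n * k_B)
}

#' Run independent replicas
#'
#' Replicas share parameters and topology and differ only in their seeds
#' (initial placement, initial velocities, thermostat noise).  A short
#' zero-temperature relaxation precedes production so random placements start
#' from a locally relaxed geometry.
#'
#' @param model,topology,params model objects.
#' @param config `sim_config`; one replica per entry of `config$seeds`.
#' @param relax_steps zero-temperature pre-relaxation steps.
#' @param force allow duplicate seeds (for control experiments).
#' @return list with `trajectories` (list of `cg_trajectory`) and `manifest`
#'   (seeds, configuration, parameters, package version).
#' @export
run_replicas <- function(model, topology, config = sim_config(),
                         params = ff_params(), relax_steps = 2000L,
                         force = FALSE) {
  seeds <- config$seeds
  if (anyDuplicated(seeds) && !force)
    stop("replica seeds must be distinct (use force = TRUE to override)")
  trajs <- lapply(seeds, function(s) {
    if (relax_steps > 0L) {
      cfg0 <- config
      cfg0$temperature <- 0
      relax <- langevin_run(model, topology, cfg0, params, seed = s,
                            steps = relax_steps, stride = 0L)
      init <- relax$final_state$pos
      tr <- langevin_run(model, topology, config, params, init = init,
                         seed = s)
    } else {
      tr <- langevin_run(model, topology, config, params, seed = s)
    }
    tr$replica <- match(s, seeds)
    tr
  })
  manifest <- list(
    seeds = seeds,
    config = unclass(config),
    params = unclass(params),
    linkage = if (is.null(topology$link)) "free" else topology$link$type,
    package_version = as.character(utils::packageVersion("ubscape")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  list(trajectories = trajs, manifest = manifest)
}
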