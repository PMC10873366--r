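## Langevin dynamics driver: protocols, energy minimisation, BAOAB
## propagation with replicates and equilibration handling.

#' Simulation protocol
#'
#' @param timestep Integration step in ps (default 0.01 ps = 10 fs).
#' @param friction Langevin friction in 1/ps.
#' @param temperature Temperature in K.
#' @param box Cubic box edge in nm (`NULL` for non-periodic).
#' @param n_steps Number of integration steps per replicate.
#' @param save_every Save a frame every this many steps.
#' @param seed Base random seed; replicate r uses `seed + r - 1`.
#' @param replicates Number of independent replicates.
#' @param equil_fraction Leading fraction of each replicate discarded as
#'   equilibration.
#' @return Object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(timestep = 0.01, friction = 1,
                                temperature = 300, box = NULL,
                                n_steps = 1e5, save_every = 1000,
                                seed = 1, replicates = 1,
                                equil_fraction = 0.2) {
  stopifnot(timestep > 0, n_steps >= save_every,
            equil_fraction >= 0, equil_fraction < 1)
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, box = box,
                 n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every),
                 seed = as.integer(seed),
                 replicates = as.integer(replicates),
                 equil_fraction = equil_fraction),
            class = "simulation_protocol")
}

#' Named protocol presets
#'
#' `"smoke"` (10 ns), `"desk"` (2 x 200 ns) and `"paper"`
#' (4 x 5 us, intended for cluster hardware) presets differing only in
#' length and replicate count.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [simulation_protocol()].
#' @return A `simulation_protocol`.
#' @export
protocol_preset <- function(name = c("smoke", "desk", "paper"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    smoke = list(n_steps = 1e6, save_every = 1000, replicates = 1,
                 equil_fraction = 0.2),
    desk  = list(n_steps = 2e7, save_every = 10000, replicates = 2,
                 equil_fraction = 0.2),
    paper = list(n_steps = 5e8, save_every = 100000, replicates = 4,
                 equil_fraction = 0.2))
  do.call(simulation_protocol, utils::modifyList(base, list(...)))
}

#' Energy minimisation
#'
#' Steepest descent with backtracking line search; the energy is
#' monotone non-increasing and iteration stops on a force-norm
#' tolerance.
#'
#' @param topology A `cg_topology`.
#' @param coords Starting coordinates (default: topology reference).
#' @param electrostatics An [electrostatics_model()].
#' @param box Cubic box edge (nm) or `NULL`.
#' @param max_iter Maximum iterations.
#' @param ftol Convergence threshold on the max force component
#'   (kJ/mol/nm).
#' @return List with minimised `coords`, final `energy`, `iterations`.
#' @export
minimize <- function(topology, coords = NULL,
                     electrostatics = electrostatics_model(),
                     box = NULL, max_iter = 2000, ftol = 10) {
  stopifnot(inherits(topology, "cg_topology"))
  if (is.null(coords)) coords <- topology$xyz0
  pack <- .pack_topology(topology, electrostatics)
  out <- .cg_minimize(as.numeric(t(as.matrix(coords))), pack,
                      if (is.null(box)) -1 else box, as.integer(max_iter),
                      ftol, 0.005)
  out$coords <- t(out$coords)
  out
}

#' Run a Langevin dynamics simulation
#'
#' BAOAB propagation of a coarse-grained topology at constant
#' temperature, optionally in a periodic cubic box.  Each replicate is
#' seeded independently and deterministically; frames within the
#' leading `equil_fraction` of each replicate are marked as
#' equilibration.
#'
#' @param topology A `cg_topology`.
#' @param protocol A [simulation_protocol()].
#' @param electrostatics An [electrostatics_model()].
#' @param start Starting coordinates (default: topology reference).
#' @param minimize_first Run energy minimisation before dynamics?
#' @return Object of class `cg_trajectory`: list with `frames`
#'   (n_frames x n_beads x 3 array, nm), `times` (ps), `replicate`,
#'   `equilibrated` (logical per frame), `epot`, `ekin`, `topology`,
#'   `protocol`.
#' @export
run_simulation <- function(topology, protocol,
                           electrostatics = electrostatics_model(),
                           start = NULL, minimize_first = TRUE) {
  stopifnot(inherits(topology, "cg_topology"),
            inherits(protocol, "simulation_protocol"))
  if (is.null(start)) start <- topology$xyz0
  start <- as.matrix(start)
  n <- nrow(topology$beads)
  if (minimize_first)
    start <- minimize(topology, start, electrostatics,
                      box = protocol$box)$coords
  pack <- .pack_topology(topology, electrostatics)
  boxv <- if (is.null(protocol$box)) -1 else protocol$box
  frames <- list(); times <- list(); rep_id <- list(); eq <- list()
  epot <- list(); ekin <- list()
  for (r in seq_len(protocol$replicates)) {
    out <- .cg_langevin(as.numeric(t(start)), pack, boxv,
                        protocol$timestep, protocol$friction,
                        protocol$temperature, protocol$n_steps,
                        protocol$save_every,
                        protocol$seed + r - 1L, NULL)
    nf <- out$n_frames
    arr <- aperm(array(out$frames[seq_len(nf * 3 * n)], c(3, n, nf)),
                 c(3, 2, 1))
    frames[[r]] <- arr
    times[[r]] <- out$times[seq_len(nf)]
    rep_id[[r]] <- rep(r, nf)
    eq[[r]] <- seq_len(nf) <= protocol$equil_fraction * nf
    epot[[r]] <- out$epot[seq_len(nf)]
    ekin[[r]] <- out$ekin[seq_len(nf)]
  }
  all_frames <- do.call(abind3, frames)
  structure(list(frames = all_frames, times = unlist(times),
                 replicate = unlist(rep_id),
                 equilibrated = !unlist(eq),
                 epot = unlist(epot), ekin = unlist(ekin),
                 topology = topology, protocol = protocol),
            class = "cg_trajectory")
}

## bind 3-d arrays along dim 1 (no abind dependency)
abind3 <- function(...) {
  arrs <- list(...)
  if (length(arrs) == 1) return(arrs[[1]])
  n1 <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(NA_real_, c(n1, dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
  at <- 1
  for (a in arrs) {
    out[at:(at + dim(a)[1] - 1), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("CG trajectory:", dim(x$frames)[1], "frames,", dim(x$frames)[2],
      "beads,", max(x$replicate), "replicate(s),",
      sum(x$equilibrated), "equilibrated frames\n")
  invisible(x)
}

#' Equilibrated frames of a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @return The frame array restricted to post-equilibration frames.
#' @export
equilibrated_frames <- function(traj) {
  traj$frames[traj$equilibrated, , , drop = FALSE]
}
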