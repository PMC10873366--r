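## shared fixtures built in code

## minimal hand-built topology for force/integrator tests
mini_topology <- function(n, xyz,
                          bonds = NULL, angles = NULL, dihedrals = NULL,
                          pairs = NULL, charge = rep(0, n), mass = 100,
                          class = rep(1L, n), eps_pp_kT = 0.16) {
  e <- function(x, d) if (is.null(x)) d else x
  beads <- data.frame(atom = "CA", resid = seq_len(n), restype = "S",
                      chain = "A", kind = "protein",
                      mass = rep_len(mass, n), charge = charge,
                      class = class, disordered = TRUE)
  params <- cg_default_params()
  params$eps_pp_kT <- eps_pp_kT
  structure(list(
    beads = beads, xyz0 = xyz,
    bonds = e(bonds, data.frame(i = integer(), j = integer(),
                                k = numeric(), d0 = numeric())),
    angles = e(angles, data.frame(i = integer(), j = integer(),
                                  k = integer(), kt = numeric(),
                                  t0 = numeric())),
    dihedrals = e(dihedrals, data.frame(i = integer(), j = integer(),
                                        k = integer(), l = integer(),
                                        mult = integer(),
                                        k_dih = numeric(),
                                        delta = numeric())),
    pairs = e(pairs, data.frame(i = integer(), j = integer(),
                                type = character(), form = integer(),
                                eps = numeric(), sigma = numeric())),
    params = params), class = "cg_topology")
}

## independent fixed-grid trapezoid oracle for <E> (Eq. 3)
trapezoid_mean_E <- function(dist, model, n_grid = 20000) {
  r <- seq(1e-6, 5 * dist$R, length.out = n_grid)
  y <- forster_efficiency(r, model) * saw_pdf(r, dist)
  sum((y[-1] + y[-n_grid]) / 2 * diff(r))
}

## finite-difference force oracle
fd_force_check <- function(topo, coords, electro, n_trials = 25,
                           h = 1e-6) {
  pe <- potential_energy(coords, topo, electro)
  err <- 0
  for (t in seq_len(n_trials)) {
    i <- sample(nrow(coords), 1); k <- sample(3, 1)
    xp <- coords; xp[i, k] <- xp[i, k] + h
    xm <- coords; xm[i, k] <- xm[i, k] - h
    fn <- -(potential_energy(xp, topo, electro)$energy -
              potential_energy(xm, topo, electro)$energy) / (2 * h)
    err <- max(err, abs(fn - pe$forces[i, k]) / max(abs(fn), 1))
  }
  err
}

## synthetic trajectory with given frames (for ensemble tests)
fake_trajectory <- function(frames, topology = NULL, dt = 1) {
  nf <- dim(frames)[1]
  if (is.null(topology)) {
    n <- dim(frames)[2]
    topology <- mini_topology(n, frames[1, , ])
  }
  structure(list(frames = frames, times = seq_len(nf) * dt,
                 replicate = rep(1L, nf),
                 equilibrated = rep(TRUE, nf),
                 epot = numeric(nf), ekin = numeric(nf),
                 topology = topology,
                 protocol = simulation_protocol(n_steps = nf,
                                                save_every = 1)),
            class = "cg_trajectory")
}
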