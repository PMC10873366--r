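## Synthetic-data generators with known ground truth: photon streams,
## titration series, nsFCS telegraph/diffusive photon emitters, and toy
## CG structures (compact folded cluster + disordered tails; ideal
## B-form CG DNA).

#' Specification for the synthetic photon-stream generator
#'
#' @param E_true True transfer efficiencies, one per species.
#' @param fractions Species fractions (same length; donor-only species
#'   have `donor_only = TRUE`); must sum to 1 with any donor-only
#'   fraction included.
#' @param donor_only Logical per species: molecule lacks an active
#'   acceptor (detected E ~ 0 and no acceptor-excitation signal).
#' @param n_bursts Number of molecule transits to generate.
#' @param burst_size_mean Mean photons per burst (donor excitation).
#' @param aex_fraction Mean acceptor-excitation photons per burst as a
#'   fraction of the donor-excitation photons (PIE).
#' @param interphoton_mean Mean interphoton time within a burst (s).
#' @param interburst_mean Mean gap between bursts (s).
#' @param background Background count rate added uniformly (Hz) across
#'   channels.
#' @param tau_D Intrinsic donor lifetime (ns).
#' @param tau_A Acceptor lifetime (ns).
#' @param crosstalk,direct_excitation,gamma Corruption factors applied
#'   when generating counts (matching [correction_set()] semantics).
#' @param seed Random seed.
#' @return Object of class `photon_generator_spec`.
#' @export
photon_generator_spec <- function(E_true = 0.43, fractions = 1,
                                  donor_only = rep(FALSE,
                                                   length(E_true)),
                                  n_bursts = 1000,
                                  burst_size_mean = 80,
                                  aex_fraction = 0.5,
                                  interphoton_mean = 10e-6,
                                  interburst_mean = 5e-3,
                                  background = 0, tau_D = 2.8,
                                  tau_A = 1.5,
                                  crosstalk = 0, direct_excitation = 0,
                                  gamma = 1, seed = 1) {
  stopifnot(length(E_true) == length(fractions),
            length(donor_only) == length(E_true),
            abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0),
            background >= 0)
  structure(as.list(environment()), class = "photon_generator_spec")
}

#' Generate a synthetic photon stream with ground-truth labels
#'
#' Bursts of exponentially spaced photons; per-photon channel drawn
#' from the species' corrupted efficiency, donor microtimes
#' exponential with effective lifetime \eqn{\tau_D (1 - E)} (delta
#' instrument response).  PIE acceptor-excitation photons are appended
#' to each burst for species with an active acceptor.  The true species
#' of every burst is retained for filter validation.
#'
#' @param spec A [photon_generator_spec()].
#' @return List with `stream` (a [photon_stream()]) and `labels` (data
#'   frame with the true species and E of every burst).
#' @export
generate_photon_stream <- function(spec) {
  stopifnot(inherits(spec, "photon_generator_spec"))
  set.seed(spec$seed)
  period <- 25
  ns <- length(spec$E_true)
  species <- sample.int(ns, spec$n_bursts, replace = TRUE,
                        prob = spec$fractions)
  t0 <- cumsum(stats::rexp(spec$n_bursts, 1 / spec$interburst_mean))
  all_t <- list(); all_ch <- list(); all_ex <- list(); all_mt <- list()
  for (b in seq_len(spec$n_bursts)) {
    sp <- species[b]
    E <- if (spec$donor_only[sp]) 0 else spec$E_true[sp]
    nph <- stats::rpois(1, spec$burst_size_mean)
    if (nph == 0) next
    tt <- t0[b] + cumsum(stats::rexp(nph, 1 / spec$interphoton_mean))
    ## detected donor and acceptor intensities: donor emits (1-E), of
    ## which a crosstalk fraction lands in the acceptor channel; the
    ## gamma factor models the acceptor/donor detection-yield imbalance
    iD <- (1 - E) * (1 - spec$crosstalk)
    iA <- E * spec$gamma + (1 - E) * spec$crosstalk
    pA <- iA / (iA + iD)
    ch <- ifelse(stats::runif(nph) < pA, "acceptor", "donor")
    mt <- ifelse(ch == "donor",
                 stats::rexp(nph, 1 / (spec$tau_D * (1 - E) + 1e-6)),
                 stats::rexp(nph, 1 / spec$tau_A))
    ex <- rep("donor", nph)
    ## acceptor-excitation (PIE) photons
    if (!spec$donor_only[sp]) {
      naa <- stats::rpois(1, spec$burst_size_mean * spec$aex_fraction)
      if (naa > 0) {
        ta <- t0[b] + stats::runif(naa, 0, max(tt) - t0[b])
        tt <- c(tt, ta)
        ch <- c(ch, rep("acceptor", naa))
        ex <- c(ex, rep("acceptor", naa))
        mt <- c(mt, stats::rexp(naa, 1 / spec$tau_A))
      }
      ## direct excitation: extra acceptor photons under donor excitation
      if (spec$direct_excitation > 0 && naa > 0) {
        nde <- stats::rbinom(1, naa, spec$direct_excitation)
        if (nde > 0) {
          td <- t0[b] + stats::runif(nde, 0, max(tt) - t0[b])
          tt <- c(tt, td); ch <- c(ch, rep("acceptor", nde))
          ex <- c(ex, rep("donor", nde))
          mt <- c(mt, stats::rexp(nde, 1 / spec$tau_A))
        }
      }
    }
    o <- order(tt)
    all_t[[b]] <- tt[o]; all_ch[[b]] <- ch[o]; all_ex[[b]] <- ex[o]
    all_mt[[b]] <- mt[o]
  }
  tt <- unlist(all_t); ch <- unlist(all_ch); ex <- unlist(all_ex)
  mt <- unlist(all_mt)
  if (spec$background > 0) {
    tspan <- max(tt)
    nbg <- stats::rpois(1, spec$background * tspan)
    tb <- sort(stats::runif(nbg, 0, tspan))
    tt <- c(tt, tb)
    ch <- c(ch, sample(c("donor", "acceptor"), nbg, replace = TRUE))
    ex <- c(ex, sample(c("donor", "acceptor"), nbg, replace = TRUE))
    mt <- c(mt, stats::runif(nbg, 0, period))
  }
  o <- order(tt)
  stream <- photon_stream(tt[o], ch[o], ex[o],
                          pmin(mt[o], period * 0.999), period = period)
  list(stream = stream,
       labels = data.frame(burst = seq_len(spec$n_bursts),
                           species = species,
                           donor_only = spec$donor_only[species],
                           E_true = ifelse(spec$donor_only[species], 0,
                                           spec$E_true[species]),
                           t_start = t0))
}

#' Generate photons from a two-state telegraph FRET process
#'
#' A molecule switches between two efficiencies at rate `k_switch`
#' (each direction); photons are emitted as a Poisson process and
#' assigned to the acceptor channel with the state's efficiency.  The
#' donor-acceptor cross-correlation of such a stream decays on the
#' telegraph correlation time \eqn{1/(2 k)}.
#'
#' @param E_states Efficiencies of the two states.
#' @param k_switch Switching rate per direction (1/s).
#' @param rate Total photon detection rate (1/s).
#' @param t_total Total duration (s).
#' @param seed Random seed.
#' @return List of sorted arrival times `t_donor`, `t_acceptor` (s).
#' @export
generate_telegraph_photons <- function(E_states = c(0.2, 0.8),
                                       k_switch = 1 / (2 * 150e-9),
                                       rate = 5e6, t_total = 0.05,
                                       seed = 1) {
  set.seed(seed)
  ## state switch times
  nsw <- stats::rpois(1, k_switch * t_total * 1.2) + 10
  sw <- cumsum(stats::rexp(nsw, k_switch))
  sw <- sw[sw < t_total]
  bounds <- c(0, sw, t_total)
  state0 <- sample(1:2, 1)
  nph <- stats::rpois(1, rate * t_total)
  tt <- sort(stats::runif(nph, 0, t_total))
  iv <- findInterval(tt, bounds)
  st <- ifelse(iv %% 2 == 1, state0, 3 - state0)
  E <- E_states[st]
  acc <- stats::runif(nph) < E
  list(t_donor = tt[!acc], t_acceptor = tt[acc])
}

#' Generate photons from diffusive chain dynamics on a SAW-nu PMF
#'
#' Simulates overdamped diffusion of the inter-dye distance on the
#' potential of mean force \eqn{-k_BT\ln P(r)} and emits photons whose
#' acceptor probability is the instantaneous Foerster efficiency.
#' Closed-loop companion of [reconfiguration_time()].
#'
#' @param dist A [saw_distribution()].
#' @param D Diffusion coefficient (nm^2/ns).
#' @param model A [forster_model()].
#' @param rate Photon rate (1/s).
#' @param t_total Duration (s).
#' @param dt Integration step (ns).
#' @param seed Random seed.
#' @return List of sorted arrival times `t_donor`, `t_acceptor` (s).
#' @export
generate_diffusive_photons <- function(dist, D, model = forster_model(),
                                       rate = 5e6, t_total = 0.05,
                                       dt = 1, seed = 1) {
  r <- seq(1e-3 * dist$R, 4 * dist$R, length.out = 400)
  lp <- log(pmax(saw_pdf(r, dist), 1e-300))
  out <- .simulate_diffusive_photons(r, lp, D, dt, t_total * 1e9,
                                     rate * 1e-9, model$R0,
                                     as.integer(seed))
  tt <- out$time * 1e-9
  list(t_donor = tt[out$channel == 1], t_acceptor = tt[out$channel == 2])
}

#' Generate a synthetic titration series from a named forward model
#'
#' Evaluates the chosen model on a log-spaced concentration grid and
#' adds Gaussian noise; the ground truth is stored as an attribute.
#'
#' @param model `"denaturant"`, `"isotherm"` or `"nmr-shift"`.
#' @param params Named list of true parameters: denaturant needs
#'   `E0`, `dE`, `Ka`; isotherm needs `KD`, `cY_tot`; nmr-shift needs
#'   `KD`, `ddmax`, `P_tot`.
#' @param n Number of concentration points.
#' @param noise Gaussian noise standard deviation (absolute, in
#'   observable units).
#' @param conc_range Concentration range (M), log-spaced.
#' @param seed Random seed.
#' @return A [titration_series()] with attribute `truth`.
#' @export
generate_titration_series <- function(model = c("denaturant", "isotherm",
                                                "nmr-shift"),
                                      params, n = 10, noise = 0,
                                      conc_range = NULL, seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  if (is.null(conc_range))
    conc_range <- switch(model,
      denaturant = c(0.05, 6),
      isotherm = params$KD * c(0.02, 50),
      `nmr-shift` = params$KD * c(0.05, 20))
  conc <- if (model == "denaturant") {
    ## denaturant titrations use a linear concentration ladder
    seq(0, conc_range[2], length.out = n)
  } else {
    exp(seq(log(conc_range[1]), log(conc_range[2]), length.out = n))
  }
  y <- switch(model,
    denaturant = (params$E0 + params$dE * params$Ka * conc) /
      (1 + params$Ka * conc),
    isotherm = isotherm_theta(conc, params$KD, params$cY_tot),
    `nmr-shift` = shift_titration_model(conc, params$KD, params$ddmax,
                                        params$P_tot))
  yn <- y + stats::rnorm(n, 0, noise)
  kind <- switch(model, denaturant = "efficiency",
                 isotherm = "fraction_bound", `nmr-shift` = "shift")
  out <- titration_series(conc, yn,
                          sd = if (noise > 0) rep(noise, n) else NULL,
                          kind = kind)
  attr(out, "truth") <- params
  out
}

#' Toy-structure generator specification
#'
#' The toy protein mimics the statistical architecture the pipeline
#' assumes -- a compact folded domain with net positive charge flanked
#' by disordered tails with balanced charges -- without reproducing any
#' real fold.
#'
#' @param folded_size Beads in the folded cluster.
#' @param n_tail Tail length in residues (C-terminal tail).
#' @param n_tail_n N-terminal tail length.
#' @param folded_charge Net charge of the folded domain.
#' @param tail_charges Number of positive and negative residues placed
#'   in the C-terminal tail (net zero by default).
#' @param dna_bp DNA duplex length in base pairs.
#' @param bond_length Calpha-Calpha bond length (nm).
#' @param seed Random seed.
#' @return Object of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(folded_size = 80, n_tail = 195,
                               n_tail_n = 0, folded_charge = 13,
                               tail_charges = 9, dna_bp = 147,
                               bond_length = 0.38, seed = 1) {
  structure(as.list(environment()), class = "toy_structure_spec")
}

## serpentine walk through a cubic lattice: compact, chain-connected
.serpentine <- function(n, a) {
  side <- ceiling(n^(1 / 3))
  xyz <- matrix(0, n, 3)
  k <- 1
  row <- 0 # global row counter keeps the x sweep continuous
  for (z in 0:(side - 1)) {
    for (yy in 0:(side - 1)) {
      y <- if (z %% 2 == 0) yy else side - 1 - yy
      xs <- 0:(side - 1)
      if (row %% 2 == 1) xs <- rev(xs)
      row <- row + 1
      for (x in xs) {
        if (k > n) break
        xyz[k, ] <- c(x, y, z) * a
        k <- k + 1
      }
    }
  }
  xyz
}

## self-avoiding random-walk tail grown from a starting point
.saw_tail <- function(n, start, direction, a, avoid, min_dist = 0.36,
                      max_retry = 200) {
  xyz <- matrix(0, n, 3)
  prev <- start
  dir <- direction / sqrt(sum(direction^2))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      step <- dir + stats::rnorm(3, 0, 0.7)
      step <- step / sqrt(sum(step^2)) * a
      cand <- prev + step
      pts <- rbind(avoid, if (i > 1) xyz[1:(i - 1), , drop = FALSE])
      if (min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 3,
                                         byrow = TRUE))^2))) >= min_dist) {
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("clash-free tail placement failed after ",
                      max_retry, " retries at residue ", i)
    prev <- cand
  }
  xyz
}

#' Build a toy protein: compact folded cluster with disordered tails
#'
#' The folded domain is a serpentine walk through a compact cubic
#' lattice (so consecutive beads stay bonded and the domain is dense in
#' native contacts); tails are self-avoiding random walks.  Charged
#' residues (K/R/D/E) are placed to realise the requested net charges;
#' all other residues are serine/glycine.
#'
#' @param spec A [toy_structure_spec()].
#' @return List with the [cg_structure()] (`structure`), the residue
#'   index ranges of the disordered tails (`disordered`), and the
#'   sequence.
#' @export
generate_toy_protein <- function(spec = toy_structure_spec()) {
  set.seed(spec$seed)
  a <- spec$bond_length
  if (spec$folded_size > 0) {
    fold <- .serpentine(spec$folded_size, a)
    ## jitter off the exact lattice: real folds have no straight
    ## collinear runs, and bonded terms take their equilibria from the
    ## built structure anyway
    fold <- fold + matrix(stats::rnorm(length(fold), 0, 0.03),
                          nrow(fold), 3)
    fold <- fold - matrix(colMeans(fold), nrow(fold), 3, byrow = TRUE)
  } else {
    fold <- matrix(0, 1, 3) # seed point for an isolated IDR chain
  }
  parts <- list()
  if (spec$n_tail_n > 0) {
    tl <- .saw_tail(spec$n_tail_n, fold[1, ], c(-1, -1, -1) , a, fold)
    parts$ntail <- tl[rev(seq_len(nrow(tl))), , drop = FALSE]
  }
  if (spec$folded_size > 0) parts$fold <- fold
  if (spec$n_tail > 0)
    parts$ctail <- .saw_tail(spec$n_tail, fold[nrow(fold), ],
                             c(1, 1, 1), a,
                             rbind(if (!is.null(parts$ntail))
                               parts$ntail, fold))
  xyz <- do.call(rbind, parts)
  n <- nrow(xyz)
  ## sequence: folded domain carries +folded_charge via K residues;
  ## C tail gets tail_charges K and tail_charges E (net zero)
  seqv <- rep("S", n)
  if (spec$folded_size > 0) {
    i_fold <- spec$n_tail_n + seq_len(spec$folded_size)
    kpos <- i_fold[round(seq(2, spec$folded_size - 1,
                             length.out = spec$folded_charge))]
    seqv[kpos] <- "K"
  }
  if (spec$n_tail > 0 && spec$tail_charges > 0) {
    i_tail <- spec$n_tail_n + spec$folded_size + seq_len(spec$n_tail)
    sl <- round(seq(3, spec$n_tail - 2,
                    length.out = 2 * spec$tail_charges))
    seqv[i_tail[sl[seq(1, length(sl), 2)]]] <- "K"
    seqv[i_tail[sl[seq(2, length(sl), 2)]]] <- "E"
  }
  disordered <- list()
  if (spec$n_tail_n > 0) disordered$ntail <- seq_len(spec$n_tail_n)
  if (spec$n_tail > 0)
    disordered$ctail <- spec$n_tail_n + spec$folded_size +
      seq_len(spec$n_tail)
  list(structure = cg_structure(xyz, rep("CA", n), seq_len(n), seqv,
                                kind = "protein"),
       disordered = disordered, sequence = seqv)
}

#' Generate an ideal B-form CG DNA duplex
#'
#' Three beads per nucleotide (P, C4', N1) placed on an ideal B-form
#' helix: rise 0.34 nm, twist 34.3 deg per base pair (10.5 bp/turn).
#' Both strands carry a 5'-terminal phosphate (one P bead per
#' nucleotide).  Watson-Crick partners are annotated via the `pair_id`
#' attribute.
#'
#' @param n_bp Number of base pairs.
#' @param sequence Optional base sequence of strand A (sampled
#'   uniformly when `NULL`).
#' @param seed Seed used only when sampling a sequence.
#' @return A [cg_structure()] of kind `"dna"` with `pair_id` attribute.
#' @export
generate_dna_duplex <- function(n_bp = 147, sequence = NULL, seed = 1) {
  stopifnot(n_bp >= 2)
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- sample(c("A", "C", "G", "T"), n_bp, replace = TRUE)
  }
  stopifnot(length(sequence) == n_bp)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  rise <- 0.34; twist <- 34.3 * pi / 180
  rN <- 0.30; rS <- 0.85; rP <- 0.95
  offS <- 70 * pi / 180; offP <- offS + 17 * pi / 180
  zP <- -0.17
  bead <- function(r, phi, z) c(r * cos(phi), r * sin(phi), z)
  xyz <- list(); atom <- c(); resid <- c(); restype <- c(); chain <- c()
  pair_id <- c()
  ## strand A, 5' -> 3' with increasing z
  for (i in seq_len(n_bp)) {
    th <- (i - 1) * twist; z <- (i - 1) * rise
    xyz[[length(xyz) + 1]] <- rbind(bead(rP, th + offP, z + zP),
                                    bead(rS, th + offS, z),
                                    bead(rN, th, z))
    atom <- c(atom, "P", "C4'", "N1")
    resid <- c(resid, rep(i, 3)); restype <- c(restype,
                                               rep(sequence[i], 3))
    chain <- c(chain, rep("A", 3)); pair_id <- c(pair_id, i)
  }
  ## strand B, antiparallel (listed 5' -> 3', i.e. decreasing z)
  phase2 <- 154 * pi / 180
  for (k in seq_len(n_bp)) {
    i <- n_bp + 1 - k   # paired bp index
    th <- (i - 1) * twist; z <- (i - 1) * rise
    xyz[[length(xyz) + 1]] <- rbind(bead(rP, th + phase2 + offP, z - zP),
                                    bead(rS, th + phase2 + offS, z),
                                    bead(rN, th + phase2, z))
    atom <- c(atom, "P", "C4'", "N1")
    resid <- c(resid, rep(k, 3))
    restype <- c(restype, rep(unname(comp[sequence[i]]), 3))
    chain <- c(chain, rep("B", 3)); pair_id <- c(pair_id, i)
  }
  out <- cg_structure(do.call(rbind, xyz), atom, resid, restype, chain,
                      kind = "dna")
  attr(out, "pair_id") <- pair_id
  out
}

#' Build the full set of toy structures (protein, DNA, docked complex)
#'
#' Generates the toy protein and an ideal duplex, then docks the DNA
#' next to the folded domain so that at least one residue-nucleotide
#' contact falls below 0.5 nm (a native protein-DNA contact).
#'
#' @param spec A [toy_structure_spec()].
#' @return List with `protein` (as from [generate_toy_protein()]),
#'   `dna` (a [cg_structure()]), and `complex` (list of repositioned
#'   `protein` and `dna` structures).
#' @export
build_toy_structures <- function(spec = toy_structure_spec()) {
  prot <- generate_toy_protein(spec)
  dna <- generate_dna_duplex(spec$dna_bp, seed = spec$seed)
  ## dock: translate the DNA so its mid-helix sits 0.45 nm from a
  ## folded-domain surface bead
  i_fold <- (if (is.null(prot$disordered$ntail)) 0 else
    length(prot$disordered$ntail)) + seq_len(spec$folded_size)
  pxyz <- prot$structure$xyz
  surf <- i_fold[which.max(pxyz[i_fold, 1])]
  target <- pxyz[surf, ] + c(0.45 + 0.0, 0, 0)
  mid_bp <- ceiling(spec$dna_bp / 2)
  key <- paste(dna$chain, dna$resid)
  iN1 <- which(dna$atom == "N1" & dna$chain == "A" &
                 dna$resid == mid_bp)
  shift <- target - dna$xyz[iN1, ]
  dna_c <- dna
  dna_c$xyz <- dna$xyz + matrix(shift, nrow(dna$xyz), 3, byrow = TRUE)
  attr(dna_c, "pair_id") <- attr(dna, "pair_id")
  list(protein = prot, dna = dna, complex = list(protein = prot,
                                                 dna = dna_c))
}

#' Write a CG structure to a PDB file
#'
#' @param struct A [cg_structure()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_cg_pdb <- function(struct, file) {
  stopifnot(inherits(struct, "cg_structure"))
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  resname <- if (struct$kind == "protein") aa3[struct$restype]
             else paste0("D", struct$restype)
  bio3d::write.pdb(file = file, xyz = as.numeric(t(struct$xyz)) * 10,
                   type = "ATOM", resno = struct$resid,
                   resid = resname, chain = struct$chain,
                   elety = struct$atom)
  invisible(file)
}
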