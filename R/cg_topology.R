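## Coarse-grained topologies: Calpha protein beads, three-bead DNA
## (P/C4'/N1), native-contact detection, Debye-Hueckel electrostatics.

## amino-acid average masses (g/mol) and bead charges
.aa_mass <- c(A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
              E = 129.12, Q = 128.13, G = 57.05, H = 137.14, I = 113.16,
              L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
              S = 87.08, T = 101.10, W = 186.21, Y = 163.18, V = 99.13)
.aa_charge <- function(aa) {
  ch <- rep(0, length(aa))
  ch[aa %in% c("K", "R")] <- 1
  ch[aa %in% c("D", "E")] <- -1
  ch[aa == "H"] <- 0.5
  ch
}
## DNA bead masses: nucleotide split across phosphate, sugar, base
.dna_mass <- c(P = 95.0, `C4'` = 115.0, N1 = 120.0)

## bead classes for the generic nonbonded table
.CLS <- c(protein_folded = 0L, protein_idr = 1L, dna_P = 2L,
          dna_C4 = 3L, dna_N1 = 4L)

#' Coarse-grained structure container
#'
#' A minimal bead-level structure: coordinates plus per-bead annotation.
#'
#' @param xyz n x 3 matrix of coordinates in nm.
#' @param atom Bead/atom names (`"CA"` for protein; `"P"`, `"C4'"`,
#'   `"N1"` for DNA).
#' @param resid Residue/nucleotide numbers.
#' @param restype One-letter residue or base codes.
#' @param chain Chain identifiers.
#' @param kind `"protein"` or `"dna"`.
#' @return Object of class `cg_structure`.
#' @export
cg_structure <- function(xyz, atom, resid, restype, chain = "A",
                         kind = c("protein", "dna")) {
  kind <- match.arg(kind)
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(ncol(xyz) == 3, length(atom) == n, length(resid) == n,
            length(restype) == n)
  structure(list(xyz = xyz, atom = atom, resid = resid,
                 restype = restype,
                 chain = rep_len(chain, n), kind = kind),
            class = "cg_structure")
}

#' Read a structure from a PDB file into the CG container
#'
#' Extracts protein Calpha atoms or DNA P/C4'/N1 atoms from a PDB file
#' (coordinates converted from Angstrom to nm).
#'
#' @param file Path to a PDB file.
#' @param kind `"protein"` or `"dna"`.
#' @return A [cg_structure()].
#' @export
read_cg_pdb <- function(file, kind = c("protein", "dna")) {
  kind <- match.arg(kind)
  pdb <- bio3d::read.pdb(file)
  sel <- if (kind == "protein") {
    bio3d::atom.select(pdb, elety = "CA")
  } else {
    bio3d::atom.select(pdb, elety = c("P", "C4'", "N1"))
  }
  at <- pdb$atom[sel$atom, ]
  rt <- at$resid
  if (kind == "protein") rt <- bio3d::aa321(rt)
  else rt <- sub("^D", "", rt)
  cg_structure(xyz = as.matrix(at[, c("x", "y", "z")]) / 10,
               atom = at$elety, resid = at$resno, restype = rt,
               chain = at$chain, kind = kind)
}

#' Debye-Hueckel electrostatics model
#'
#' Screened Coulomb electrostatics with dielectric constant `eps_d` and
#' Debye length computed from the ionic strength (see [debye_length()]).
#'
#' @param ionic_strength Monovalent-salt ionic strength, M.
#' @param temperature Temperature in K.
#' @param eps_d Relative dielectric constant of the solvent.
#' @param cutoff_factor Electrostatic cutoff as a multiple of the Debye
#'   length (the potential is shifted to zero there).
#' @return Object of class `electrostatics_model` with the derived
#'   `lambda_D` (nm).
#' @export
electrostatics_model <- function(ionic_strength = 0.165,
                                 temperature = 300, eps_d = 80,
                                 cutoff_factor = 4) {
  lam <- debye_length(ionic_strength, temperature, eps_d)
  structure(list(ionic_strength = ionic_strength,
                 temperature = temperature, eps_d = eps_d,
                 lambda_D = lam, cutoff = cutoff_factor * lam),
            class = "electrostatics_model")
}

#' Debye screening length
#'
#' \deqn{\lambda_D = \sqrt{\epsilon_0\epsilon_d k_B T /
#'   (2 N_A e^2 I)}}
#' with the ionic strength I converted to mol/m\eqn{^3}.  Scales as
#' \eqn{I^{-1/2}}.
#'
#' @param ionic_strength Ionic strength in M (> 0).
#' @param temperature Temperature in K.
#' @param eps_d Relative dielectric constant.
#' @return Debye length in nm.
#' @export
debye_length <- function(ionic_strength, temperature = 298,
                         eps_d = 80) {
  if (ionic_strength <= 0) stop("ionic strength must be positive")
  cc <- cg_constants
  lam_m <- sqrt(cc$eps0 * eps_d * cc$kB_SI * temperature /
                  (2 * cc$NA_const * cc$e^2 * ionic_strength * 1000))
  lam_m * 1e9
}

## default force-field parameters (kJ/mol, nm, rad)
#' Default coarse-grained force-field parameters
#'
#' Interaction strengths quoted in the literature in units of
#' \eqn{k_B T} are converted at the 300 K reference
#' (\eqn{k_B T = 2.494} kJ/mol): disordered protein pair strength
#' `eps_pp` = 0.16 \eqn{k_B T}, DNA stacking 3.0, Watson-Crick pairing
#' 3.5, non-specific DNA 0.04, native protein-DNA 2, non-native
#' protein-DNA 0.06 \eqn{k_B T}.  DNA bonded constants are the shipped
#' defaults of the persistence-length calibration (~50 nm).
#'
#' @return Named list of parameters; pass (modified) to the topology
#'   builders.
#' @export
cg_default_params <- function() {
  kt <- cg_constants$kT_ref
  list(
    ## protein bonded
    kb_protein = 8368, ktheta_protein = 83.68,
    ktheta_idr = 10, kdih_generic = 0.2,
    ## protein nonbonded
    eps_pp_kT = 0.16, sigma_pp = 0.6, eps_native_pp = 3.0,
    native_cutoff_ca = 1.2, native_min_sep = 3,
    ## DNA bonded (persistence-length calibrated)
    kb_dna = 8368, ktheta_dna = 600, kdih_dna = 60, k_support_dna = 10,
    ## DNA nonbonded
    eps_stack_kT = 3.0, eps_pair_kT = 3.5, eps_ns_kT = 0.04,
    sigma_ns = 0.45,
    ## protein-DNA
    eps_native_pd_kT = 2.0, eps_pd_kT = 0.06, sigma_pd = 0.5,
    native_cutoff_pd = 0.5,
    ## generic cutoff / neighbour skin
    rc_lj = 1.5, skin = 0.6,
    kT_ref = kt
  )
}

.angle_between <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ct)))
}

.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3],
          b1[1]*b2[2]-b1[2]*b2[1])
  n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3],
          b2[1]*b3[2]-b2[2]*b3[1])
  m <- c(n1[2]*n2[3]-n1[3]*n2[2], n1[3]*n2[1]-n1[1]*n2[3],
         n1[1]*n2[2]-n1[2]*n2[1])
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

## sequence-specific dihedral lookup shipped with the package
.dihedral_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      f <- system.file("extdata", "dihedral_params.csv",
                       package = "cgfret")
      tab <<- if (nzchar(f)) utils::read.csv(f) else NULL
    }
    tab
  }
})

.dihedral_terms_for <- function(res_j, res_k, k_fallback) {
  tab <- .dihedral_table()
  key <- paste0(res_j, res_k)
  if (!is.null(tab)) {
    hit <- tab[tab$pair == key, ]
    if (nrow(hit) == 0) {
      cl <- if (res_j == "G" || res_k == "G") "G*"
            else if (res_j == "P" || res_k == "P") "P*" else "generic"
      hit <- tab[tab$pair == cl, ]
    }
    if (nrow(hit) > 0)
      return(data.frame(mult = hit$mult, k = hit$k, delta = hit$delta))
  }
  data.frame(mult = 1:4, k = rep(k_fallback, 4), delta = rep(0, 4))
}

#' Build the Calpha protein topology
#'
#' One bead per residue at the Calpha position.  Bond lengths and angle
#' values are taken from the starting structure; dihedral terms come
#' from the bundled residue-pair table (with a uniform weak fallback);
#' lysine/arginine beads carry charge +1, aspartate/glutamate -1,
#' histidine +0.5.  Native pairs (Go recipe, 12-10-6 form with sigma
#' equal to the native Calpha distance) are assigned only within the
#' folded domain; all other protein pair interactions use the uniform
#' 12-6 term with strength `eps_pp`.
#'
#' @param structure A [cg_structure()] of kind `"protein"` with one CA
#'   bead per residue (consecutive along the chain).
#' @param disordered_ranges List of integer vectors of residue indices
#'   (positions along the chain, 1-based) that are disordered.
#' @param params Parameter list from [cg_default_params()].
#' @return Object of class `cg_topology`.
#' @export
build_protein_topology <- function(structure, disordered_ranges = list(),
                                   params = cg_default_params()) {
  stopifnot(inherits(structure, "cg_structure"),
            structure$kind == "protein")
  if (!all(structure$atom == "CA"))
    stop("protein structure must contain only CA beads (missing atoms?)")
  n <- nrow(structure$xyz)
  if (any(diff(structure$resid) != 1))
    stop("chain break: residues are not consecutive")
  xyz <- structure$xyz
  aa <- structure$restype
  disordered <- rep(FALSE, n)
  for (rg in disordered_ranges) disordered[rg] <- TRUE

  bd <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                        xyz[-n, , drop = FALSE])^2))
  if (any(bd > 0.6))
    stop("chain break: consecutive CA distance exceeds 0.6 nm")
  bonds <- data.frame(i = 1:(n - 1), j = 2:n,
                      k = params$kb_protein, d0 = bd)
  angles <- if (n >= 3) {
    t0 <- vapply(1:(n - 2), function(i)
      .angle_between(xyz[i, ] - xyz[i + 1, ], xyz[i + 2, ] - xyz[i + 1, ]),
      0)
    ## disordered backbones bend freely: soft angle springs there,
    ## structure-derived stiff ones in the folded domain
    mid <- 2:(n - 1)
    data.frame(i = 1:(n - 2), j = mid, k = 3:n,
               kt = ifelse(disordered[mid], params$ktheta_idr,
                           params$ktheta_protein),
               t0 = t0)
  } else .empty_angles()
  dihedrals <- if (n >= 4) {
    do.call(rbind, lapply(1:(n - 3), function(i) {
      terms <- .dihedral_terms_for(aa[i + 1], aa[i + 2],
                                   params$kdih_generic)
      data.frame(i = i, j = i + 1, k = i + 2, l = i + 3,
                 mult = terms$mult, k_dih = terms$k, delta = terms$delta)
    }))
  } else .empty_dihedrals()

  ## Go native pairs within the folded domain
  folded <- which(!disordered)
  pairs <- .empty_pairs()
  if (length(folded) > 1) {
    np <- detect_native_contacts(structure, cutoff = params$native_cutoff_ca,
                                 domain = "protein-protein",
                                 min_seq_sep = params$native_min_sep,
                                 subset = folded,
                                 eps = params$eps_native_pp)
    pairs <- np
  }
  beads <- data.frame(
    atom = structure$atom, resid = structure$resid, restype = aa,
    chain = structure$chain, kind = "protein",
    mass = unname(.aa_mass[aa]),
    charge = .aa_charge(aa),
    class = ifelse(disordered, .CLS["protein_idr"],
                   .CLS["protein_folded"]),
    disordered = disordered)
  if (anyNA(beads$mass)) stop("unknown residue type in sequence")
  base::structure(list(beads = beads, xyz0 = xyz, bonds = bonds,
                       angles = angles, dihedrals = dihedrals,
                       pairs = pairs, params = params),
                  class = "cg_topology")
}

.empty_pairs <- function()
  data.frame(i = integer(), j = integer(), type = character(),
             form = integer(), eps = numeric(), sigma = numeric())
.empty_angles <- function()
  data.frame(i = integer(), j = integer(), k = integer(),
             kt = numeric(), t0 = numeric())
.empty_dihedrals <- function()
  data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
             mult = integer(), k_dih = numeric(), delta = numeric())

#' Build the three-bead DNA topology
#'
#' Each nucleotide contributes P, C4' and N1 beads (one phosphate per
#' nucleotide including the 5' ends).  Phosphates carry charge -1.
#' Bonded equilibrium values come from the input duplex structure.
#' Same-strand consecutive bases interact through a stacking 12-6 term
#' (3.0 \eqn{k_B T}), Watson-Crick partner bases through a pairing term
#' (3.5 \eqn{k_B T}); all remaining DNA bead pairs use the weak
#' non-specific term (0.04 \eqn{k_B T}).  The 12-6 sigma of the stack
#' and pair terms places the potential minimum at the native distance.
#'
#' @param structure A [cg_structure()] of kind `"dna"` with beads
#'   ordered P, C4', N1 within each nucleotide, plus a `pair_id` per
#'   nucleotide marking Watson-Crick partners (as produced by
#'   [generate_dna_duplex()] or [read_cg_pdb()] for an annotated
#'   duplex).
#' @param params Parameter list from [cg_default_params()].
#' @return Object of class `cg_topology`.
#' @export
build_dna_topology <- function(structure, params = cg_default_params()) {
  stopifnot(inherits(structure, "cg_structure"), structure$kind == "dna")
  xyz <- structure$xyz
  n <- nrow(xyz)
  atom <- structure$atom
  chain <- structure$chain
  ## index beads per nucleotide
  nt_key <- paste(chain, structure$resid)
  nts <- unique(nt_key)
  idx <- lapply(nts, function(k) which(nt_key == k))
  bad <- vapply(idx, function(ii)
    !identical(atom[ii], c("P", "C4'", "N1")), TRUE)
  if (any(bad))
    stop("each nucleotide must have beads P, C4', N1 in order")
  nnt <- length(nts)
  iP <- vapply(idx, `[`, 1L, 1); iS <- vapply(idx, `[`, 1L, 2)
  iB <- vapply(idx, `[`, 1L, 3)
  nt_chain <- chain[iP]; nt_resid <- structure$resid[iP]

  ## Watson-Crick pairing from annotation
  pair_id <- attr(structure, "pair_id")
  if (is.null(pair_id))
    stop("duplex structure lacks Watson-Crick pair annotation (pair_id)")
  wc <- .wc_partners(pair_id)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  bases <- structure$restype[iB]
  mism <- bases[wc[, 1]] != comp[bases[wc[, 2]]]
  if (any(mism))
    stop("unpaired or mismatched strands: non-complementary bases at ",
         paste(which(mism)[1], collapse = ","))

  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  bonds <- list(); angles <- list(); dihedrals <- list()
  for (s in unique(nt_chain)) {
    ii <- which(nt_chain == s)
    ii <- ii[order(nt_resid[ii])]
    for (t in seq_along(ii)) {
      k <- ii[t]
      bonds[[length(bonds) + 1]] <- c(iP[k], iS[k])
      bonds[[length(bonds) + 1]] <- c(iS[k], iB[k])
      if (t < length(ii)) {
        k2 <- ii[t + 1]
        bonds[[length(bonds) + 1]] <- c(iS[k], iP[k2])
        angles[[length(angles) + 1]] <- c(iP[k], iS[k], iP[k2])
        angles[[length(angles) + 1]] <- c(iB[k], iS[k], iP[k2])
        angles[[length(angles) + 1]] <- c(iS[k], iP[k2], iS[k2])
        dihedrals[[length(dihedrals) + 1]] <-
          c(iP[k], iS[k], iP[k2], iS[k2])
        if (t < length(ii) - 0) {
          dihedrals[[length(dihedrals) + 1]] <-
            c(iS[k], iP[k2], iS[k2], iB[k2])
        }
      }
      angles[[length(angles) + 1]] <- c(iP[k], iS[k], iB[k])
    }
  }
  bonds <- do.call(rbind, bonds)
  bonds <- data.frame(i = bonds[, 1], j = bonds[, 2], k = params$kb_dna,
                      d0 = apply(bonds, 1, function(r) d(r[1], r[2])))
  am <- do.call(rbind, angles)
  angles <- data.frame(
    i = am[, 1], j = am[, 2], k = am[, 3], kt = params$ktheta_dna,
    t0 = apply(am, 1, function(r)
      .angle_between(xyz[r[1], ] - xyz[r[2], ], xyz[r[3], ] - xyz[r[2], ])))
  dm <- do.call(rbind, dihedrals)
  dihedrals <- data.frame(
    i = dm[, 1], j = dm[, 2], k = dm[, 3], l = dm[, 4], mult = 1L,
    k_dih = params$kdih_dna,
    delta = apply(dm, 1, function(r)
      .dihedral_angle(xyz[r[1], ], xyz[r[2], ], xyz[r[3], ],
                      xyz[r[4], ]) + pi))

  kt <- params$kT_ref
  pairs <- list()
  ## stacking: consecutive bases on the same strand
  for (s in unique(nt_chain)) {
    ii <- which(nt_chain == s)
    ii <- ii[order(nt_resid[ii])]
    for (t in seq_len(length(ii) - 1)) {
      b1 <- iB[ii[t]]; b2 <- iB[ii[t + 1]]
      pairs[[length(pairs) + 1]] <- data.frame(
        i = b1, j = b2, type = "stack", form = 0L,
        eps = params$eps_stack_kT * kt, sigma = d(b1, b2) / 2^(1 / 6))
    }
  }
  ## Watson-Crick pairing across strands
  for (r in seq_len(nrow(wc))) {
    b1 <- iB[wc[r, 1]]; b2 <- iB[wc[r, 2]]
    pairs[[length(pairs) + 1]] <- data.frame(
      i = min(b1, b2), j = max(b1, b2), type = "pair", form = 0L,
      eps = params$eps_pair_kT * kt, sigma = d(b1, b2) / 2^(1 / 6))
  }
  pairs <- do.call(rbind, pairs)

  ## cross-strand support bonds between paired (and diagonally
  ## adjacent) sugars: harmonic restraints that give the duplex its
  ## shear stiffness, tuned with the other bonded constants so the
  ## equilibrium persistence length is ~50 nm
  if (params$k_support_dna > 0) {
    nbp <- nrow(wc)
    sup <- rbind(
      data.frame(i = iS[wc[, 1]], j = iS[wc[, 2]]),
      data.frame(i = iS[wc[seq_len(nbp - 1), 1]],
                 j = iS[wc[seq(2, nbp), 2]]),
      data.frame(i = iS[wc[seq_len(nbp - 1), 2]],
                 j = iS[wc[seq(2, nbp), 1]]))
    sup$k <- params$k_support_dna
    sup$d0 <- vapply(seq_len(nrow(sup)),
                     function(r) d(sup$i[r], sup$j[r]), 0)
    bonds <- rbind(bonds, sup)
  }

  beads <- data.frame(
    atom = atom, resid = structure$resid, restype = structure$restype,
    chain = chain, kind = "dna",
    mass = unname(.dna_mass[atom]),
    charge = ifelse(atom == "P", -1, 0),
    class = unname(c(P = .CLS[["dna_P"]], `C4'` = .CLS[["dna_C4"]],
                     N1 = .CLS[["dna_N1"]])[atom]),
    disordered = FALSE)
  out <- base::structure(
    list(beads = beads, xyz0 = xyz, bonds = bonds, angles = angles,
         dihedrals = dihedrals, pairs = pairs, params = params),
    class = "cg_topology")
  attr(out, "pair_id") <- pair_id
  out
}

## pair_id vector (per nucleotide) -> matrix of index pairs (once each)
.wc_partners <- function(pair_id) {
  ids <- unique(pair_id[!is.na(pair_id)])
  out <- t(vapply(ids, function(id) which(pair_id == id), c(1L, 2L)))
  out
}

#' Detect native contacts
#'
#' For protein-protein contacts (within a folded domain) two residues
#' are native partners when their bead distance falls below `cutoff`
#' (with a minimum sequence separation); the pair enters the 12-10-6
#' list with sigma equal to the native distance.  For protein-DNA
#' contacts a residue and a nucleotide are native partners when any of
#' their atoms/beads approach within `cutoff` (0.5 nm); those pairs get
#' strength 2 \eqn{k_B T} and sigma 0.5 nm, applied between the residue
#' bead and the nucleotide's C4' bead.
#'
#' @param structure A [cg_structure()] (protein), or for
#'   `"protein-dna"` the protein structure.
#' @param dna For `"protein-dna"`, the DNA [cg_structure()].
#' @param cutoff Contact cutoff in nm.
#' @param domain `"protein-protein"` or `"protein-dna"`.
#' @param min_seq_sep Minimum |i - j| along the chain (protein-protein).
#' @param subset Residue indices eligible for contacts (protein-protein).
#' @param eps Native contact strength in kJ/mol (protein-protein).
#' @param params Parameter list (protein-DNA strengths).
#' @return Pair data frame (`i`, `j`, `type`, `form`, `eps`, `sigma`);
#'   for `"protein-dna"` indices refer to protein residue beads and DNA
#'   C4' beads in their respective structures.
#' @export
detect_native_contacts <- function(structure, dna = NULL, cutoff = 0.5,
                                   domain = c("protein-protein",
                                              "protein-dna"),
                                   min_seq_sep = 3, subset = NULL,
                                   eps = 3.0,
                                   params = cg_default_params()) {
  domain <- match.arg(domain)
  if (nrow(structure$xyz) == 0) stop("empty structure")
  if (domain == "protein-protein") {
    xyz <- structure$xyz
    n <- nrow(xyz)
    if (is.null(subset)) subset <- seq_len(n)
    dm <- as.matrix(stats::dist(xyz[subset, , drop = FALSE]))
    hits <- which(dm < cutoff & upper.tri(dm), arr.ind = TRUE)
    ii <- subset[hits[, 1]]; jj <- subset[hits[, 2]]
    keep <- abs(ii - jj) >= min_seq_sep
    ii <- ii[keep]; jj <- jj[keep]
    data.frame(i = pmin(ii, jj), j = pmax(ii, jj), type = "native_pp",
               form = 1L, eps = eps,
               sigma = sqrt(rowSums((xyz[ii, , drop = FALSE] -
                                       xyz[jj, , drop = FALSE])^2)))
  } else {
    stopifnot(!is.null(dna))
    pxyz <- structure$xyz
    dxyz <- dna$xyz
    nt_key <- paste(dna$chain, dna$resid)
    nts <- unique(nt_key)
    kt <- params$kT_ref
    out <- list()
    for (ri in seq_len(nrow(pxyz))) {
      for (ni in seq_along(nts)) {
        jj <- which(nt_key == nts[ni])
        dmin <- min(sqrt(colSums((t(dxyz[jj, , drop = FALSE]) -
                                    pxyz[ri, ])^2)))
        if (dmin < cutoff) {
          jC4 <- jj[dna$atom[jj] == "C4'"]
          out[[length(out) + 1]] <- data.frame(
            i = ri, j = jC4, type = "native_pd", form = 1L,
            eps = params$eps_native_pd_kT * kt, sigma = params$sigma_pd)
        }
      }
    }
    if (length(out) == 0) return(.empty_pairs())
    do.call(rbind, out)
  }
}

#' Merge a protein and a DNA topology into a complex
#'
#' Concatenates the two topologies (DNA bead indices are offset) and
#' appends native protein-DNA pairs detected from the given structures.
#'
#' @param protein_topo,dna_topo `cg_topology` objects.
#' @param native_pd Optional precomputed protein-DNA native pair table
#'   from [detect_native_contacts()] (indices as returned there); when
#'   `NULL` contacts are detected from the stored coordinates.
#' @param params Parameter list.
#' @return A merged `cg_topology`.
#' @export
build_complex_topology <- function(protein_topo, dna_topo,
                                   native_pd = NULL,
                                   params = cg_default_params()) {
  np <- nrow(protein_topo$beads)
  off <- function(df, cols) { df[cols] <- df[cols] + np; df }
  beads <- rbind(protein_topo$beads, dna_topo$beads)
  xyz0 <- rbind(protein_topo$xyz0, dna_topo$xyz0)
  bonds <- rbind(protein_topo$bonds, off(dna_topo$bonds, c("i", "j")))
  angles <- rbind(protein_topo$angles,
                  off(dna_topo$angles, c("i", "j", "k")))
  dihedrals <- rbind(protein_topo$dihedrals,
                     off(dna_topo$dihedrals, c("i", "j", "k", "l")))
  pairs <- rbind(protein_topo$pairs, off(dna_topo$pairs, c("i", "j")))
  if (is.null(native_pd)) {
    pstr <- cg_structure(protein_topo$xyz0, protein_topo$beads$atom,
                         protein_topo$beads$resid,
                         protein_topo$beads$restype,
                         protein_topo$beads$chain, "protein")
    dstr <- cg_structure(dna_topo$xyz0, dna_topo$beads$atom,
                         dna_topo$beads$resid, dna_topo$beads$restype,
                         dna_topo$beads$chain, "dna")
    attr(dstr, "pair_id") <- attr(dna_topo, "pair_id")
    native_pd <- detect_native_contacts(pstr, dstr,
                                        cutoff = params$native_cutoff_pd,
                                        domain = "protein-dna",
                                        params = params)
  }
  if (nrow(native_pd) > 0) {
    native_pd$j <- native_pd$j + np
    pairs <- rbind(pairs, native_pd)
  }
  structure(list(beads = beads, xyz0 = xyz0, bonds = bonds,
                 angles = angles, dihedrals = dihedrals, pairs = pairs,
                 params = params),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("CG topology:", nrow(x$beads), "beads,", nrow(x$bonds), "bonds,",
      nrow(x$angles), "angles,", nrow(x$dihedrals), "dihedral terms,",
      nrow(x$pairs), "specific pairs\n")
  print(table(x$beads$kind))
  invisible(x)
}

## pack a topology for the C++ kernels (0-based indices)
.pack_topology <- function(topo, electro) {
  n <- nrow(topo$beads)
  p <- topo$params
  kt <- p$kT_ref
  ncls <- 5L
  eps_tab <- matrix(0, ncls, ncls)
  sig_tab <- matrix(0.5, ncls, ncls)
  pp <- 1:2; dna <- 3:5
  eps_tab[pp, pp] <- p$eps_pp_kT * kt;  sig_tab[pp, pp] <- p$sigma_pp
  eps_tab[dna, dna] <- p$eps_ns_kT * kt; sig_tab[dna, dna] <- p$sigma_ns
  eps_tab[pp, dna] <- p$eps_pd_kT * kt; sig_tab[pp, dna] <- p$sigma_pd
  eps_tab[dna, pp] <- p$eps_pd_kT * kt; sig_tab[dna, pp] <- p$sigma_pd

  key <- function(i, j) (pmin(i, j) - 1) * n + (pmax(i, j) - 1)
  exb <- c(key(topo$bonds$i, topo$bonds$j),
           if (nrow(topo$angles)) key(topo$angles$i, topo$angles$k),
           if (nrow(topo$dihedrals)) key(topo$dihedrals$i,
                                         topo$dihedrals$l))
  exp_ <- if (nrow(topo$pairs)) key(topo$pairs$i, topo$pairs$j) else
    numeric()
  list(charge = topo$beads$charge, mass = topo$beads$mass,
       class = as.integer(topo$beads$class),
       bonds = cbind(as.integer(topo$bonds$i - 1),
                     as.integer(topo$bonds$j - 1)),
       bond_k = topo$bonds$k, bond_d0 = topo$bonds$d0,
       angles = cbind(as.integer(topo$angles$i - 1),
                      as.integer(topo$angles$j - 1),
                      as.integer(topo$angles$k - 1)),
       angle_k = topo$angles$kt, angle_t0 = topo$angles$t0,
       dihedrals = cbind(as.integer(topo$dihedrals$i - 1),
                         as.integer(topo$dihedrals$j - 1),
                         as.integer(topo$dihedrals$k - 1),
                         as.integer(topo$dihedrals$l - 1),
                         as.integer(topo$dihedrals$mult)),
       dihedral_k = topo$dihedrals$k_dih,
       dihedral_delta = topo$dihedrals$delta,
       pairs = cbind(as.integer(topo$pairs$i - 1),
                     as.integer(topo$pairs$j - 1),
                     as.integer(topo$pairs$form)),
       pair_eps = topo$pairs$eps, pair_sigma = topo$pairs$sigma,
       table_eps = eps_tab, table_sigma = sig_tab,
       excl_bonded = sort(unique(exb)), excl_pair = sort(unique(exp_)),
       eps_d = electro$eps_d, lambda_D = electro$lambda_D,
       rc_e = electro$cutoff, rc_lj = p$rc_lj, skin = p$skin)
}

#' Potential energy, per-term breakdown and forces
#'
#' Evaluates the full coarse-grained potential (bonds, angles,
#' dihedrals, screened Coulomb, specific 12-10-6/12-6 pairs, generic
#' class-based 12-6 terms) and its analytic forces.
#'
#' @param coords n x 3 coordinate matrix (nm); defaults to the
#'   topology's reference coordinates.
#' @param topology A `cg_topology`.
#' @param electrostatics An [electrostatics_model()].
#' @param box Cubic box edge in nm, or `NULL` for no periodicity.
#' @return List with `energy` (kJ/mol), `terms` (named breakdown) and
#'   `forces` (n x 3, kJ/mol/nm).
#' @export
potential_energy <- function(coords = NULL, topology,
                             electrostatics = electrostatics_model(),
                             box = NULL) {
  stopifnot(inherits(topology, "cg_topology"))
  if (is.null(coords)) coords <- topology$xyz0
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(topology$beads))
  pack <- .pack_topology(topology, electrostatics)
  out <- .cg_energy_forces(as.numeric(t(coords)), pack,
                           if (is.null(box)) -1 else box)
  out$forces <- t(out$forces)
  out
}
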