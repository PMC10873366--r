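test_that("protein topology counts bonded terms and assigns charges", {
  ## 10-residue straight poly-G coil
  xyz <- cbind(seq(0, by = 0.38, length.out = 10), 0, 0)
  xyz[, 2] <- 0.02 * (seq_len(10) %% 2) # avoid exact collinearity
  st <- cg_structure(xyz, rep("CA", 10), 1:10, rep("G", 10),
                     kind = "protein")
  topo <- build_protein_topology(st, disordered_ranges = list(1:10))
  expect_equal(nrow(topo$bonds), 9)
  expect_equal(nrow(topo$angles), 8)
  expect_equal(length(unique(paste(topo$dihedrals$i, topo$dihedrals$j,
                                   topo$dihedrals$k,
                                   topo$dihedrals$l))), 7)
  expect_true(all(topo$beads$charge == 0))
  ## charge table: K R D E H
  st2 <- cg_structure(xyz[1:5, ], rep("CA", 5), 1:5,
                      c("K", "R", "D", "E", "H"), kind = "protein")
  topo2 <- build_protein_topology(st2, list(1:5))
  expect_equal(topo2$beads$charge, c(1, 1, -1, -1, 0.5))
})

test_that("toy folded cluster yields native pairs at their built distances", {
  toy <- generate_toy_protein(toy_structure_spec(folded_size = 60,
                                                 n_tail = 30, seed = 2))
  topo <- build_protein_topology(toy$structure, toy$disordered)
  np <- topo$pairs[topo$pairs$type == "native_pp", ]
  expect_gt(nrow(np), 20)
  expect_true(all(np$eps > 0))
  d <- sqrt(rowSums((topo$xyz0[np$i, ] - topo$xyz0[np$j, ])^2))
  expect_equal(np$sigma, d, tolerance = 1e-12)
  expect_true(all(d < 1.2))
  ## native pairs confined to the folded domain
  i_tail <- unlist(toy$disordered)
  expect_false(any(np$i %in% i_tail | np$j %in% i_tail))
})

test_that("DNA topology has the printed interaction strengths", {
  dna <- generate_dna_duplex(15, seed = 3)
  topo <- build_dna_topology(dna)
  kt <- cg_constants$kT_ref
  ## 15 bp duplex: 2*15 nucleotides x 3 beads, one P per nucleotide
  expect_equal(nrow(topo$beads), 2 * 15 * 3)
  expect_equal(sum(topo$beads$charge == -1), 30)
  expect_equal(sum(topo$beads$charge), -30)
  st <- topo$pairs[topo$pairs$type == "stack", ]
  wc <- topo$pairs[topo$pairs$type == "pair", ]
  expect_equal(nrow(st), 2 * 14)
  expect_equal(nrow(wc), 15)
  expect_equal(unique(st$eps), 3.0 * kt)
  expect_equal(unique(wc$eps), 3.5 * kt)
  ## complementary bases across every WC pair
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  b_i <- topo$beads$restype[wc$i]; b_j <- topo$beads$restype[wc$j]
  expect_true(all(b_i == comp[b_j]))
  ## mismatched strands rejected
  bad <- dna
  bad$restype[bad$chain == "B"] <- "A"
  attr(bad, "pair_id") <- attr(dna, "pair_id")
  expect_error(build_dna_topology(bad), "mismatch")
})

test_that("pair-interaction parameter table matches the model definition", {
  p <- cg_default_params()
  kt <- cg_constants$kT_ref
  expect_equal(p$eps_pp_kT, 0.16)
  expect_equal(p$sigma_pp, 0.6)
  expect_equal(p$eps_stack_kT, 3.0)
  expect_equal(p$eps_pair_kT, 3.5)
  expect_equal(p$eps_ns_kT, 0.04)
  expect_equal(p$eps_native_pd_kT, 2.0)
  expect_equal(p$eps_pd_kT, 0.06)
  expect_equal(p$sigma_pd, 0.5)
  ## 0.16 kT at the 300 K reference is ~0.4 kJ/mol
  expect_equal(0.16 * kt, 0.399, tolerance = 1e-3)
})

test_that("native-contact detection respects the 0.5 nm cutoff", {
  ## two beads at 0.45 nm -> native; at 0.55 nm -> not
  prot <- cg_structure(rbind(c(0, 0, 0)), "CA", 1, "K",
                       kind = "protein")
  mk_dna1 <- function(dx) {
    st <- cg_structure(rbind(c(dx, 0, 0), c(dx + 0.3, 0, 0),
                             c(dx + 0.6, 0, 0)),
                       c("P", "C4'", "N1"), c(1, 1, 1), rep("A", 3),
                       kind = "dna")
    st
  }
  nc1 <- detect_native_contacts(prot, mk_dna1(0.45),
                                domain = "protein-dna")
  expect_equal(nrow(nc1), 1)
  expect_equal(nc1$eps, 2.0 * cg_constants$kT_ref)
  expect_equal(nc1$sigma, 0.5)
  nc2 <- detect_native_contacts(prot, mk_dna1(0.55),
                                domain = "protein-dna")
  expect_equal(nrow(nc2), 0)
  ## protein-protein native count equals a brute-force all-pairs scan
  toy <- generate_toy_protein(toy_structure_spec(folded_size = 40,
                                                 n_tail = 0, seed = 5))
  nc <- detect_native_contacts(toy$structure, cutoff = 1.0,
                               domain = "protein-protein",
                               min_seq_sep = 3)
  xyz <- toy$structure$xyz
  brute <- 0
  for (i in 1:(nrow(xyz) - 3))
    for (j in (i + 3):nrow(xyz))
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 1.0) brute <- brute + 1
  expect_equal(nrow(nc), brute)
})

test_that("Debye length follows the square-root salt dependence", {
  ## 0.304/sqrt(I) nm at 25 C (eps_d ~ 78.5); slightly longer at 80
  expect_equal(debye_length(0.1, 298, 78.5), 0.304 / sqrt(0.1),
               tolerance = 0.01)
  expect_equal(debye_length(0.1, 298, 80), 0.96, tolerance = 0.02)
  expect_equal(debye_length(0.4), debye_length(0.1) / 2,
               tolerance = 1e-12)
  expect_equal(debye_length(0.165, 298),
               debye_length(0.1, 298) / sqrt(1.65), tolerance = 1e-12)
  expect_error(debye_length(0), "positive")
})

test_that("potential terms obey the analytic identities at sigma", {
  ## 12-10-6 native term at d = sigma equals -eps (13 - 18 + 4 = -1)
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  topo <- mini_topology(2, xyz,
                        pairs = data.frame(i = 1, j = 2, type = "n",
                                           form = 1L, eps = 2,
                                           sigma = 0.5),
                        eps_pp_kT = 0)
  el <- electrostatics_model()
  expect_equal(potential_energy(xyz, topo, el)$energy, -2,
               tolerance = 1e-12)
  ## 12-6 pair term: zero at sigma, minimum -eps at 2^(1/6) sigma
  topo6 <- mini_topology(2, xyz,
                         pairs = data.frame(i = 1, j = 2, type = "s",
                                            form = 0L, eps = 3,
                                            sigma = 0.5),
                         eps_pp_kT = 0)
  expect_equal(potential_energy(xyz, topo6, el)$energy, 0,
               tolerance = 1e-12)
  xyz_min <- rbind(c(0, 0, 0), c(0.5 * 2^(1 / 6), 0, 0))
  expect_equal(potential_energy(xyz_min, topo6, el)$energy, -3,
               tolerance = 1e-12)
})

test_that("analytic forces agree with finite differences for every term class", {
  set.seed(7)
  el <- electrostatics_model(0.165)
  ## protein system exercises bonds, angles, dihedrals, native 12-10-6,
  ## generic 12-6 and electrostatics
  toy <- generate_toy_protein(toy_structure_spec(folded_size = 25,
                                                 n_tail = 15, seed = 7))
  pt <- build_protein_topology(toy$structure, toy$disordered)
  x <- pt$xyz0 + matrix(stats::rnorm(length(pt$xyz0), 0, 0.01),
                        nrow(pt$xyz0))
  expect_lt(fd_force_check(pt, x, el), 1e-6)
  ## DNA system exercises the stack/pair lists and phosphate charges
  dna <- generate_dna_duplex(10, seed = 8)
  dt <- build_dna_topology(dna)
  xd <- dt$xyz0 + matrix(stats::rnorm(length(dt$xyz0), 0, 0.01),
                         nrow(dt$xyz0))
  expect_lt(fd_force_check(dt, xd, el), 1e-6)
})

test_that("energy is invariant under rigid translation and rotation", {
  el <- electrostatics_model(0.165)
  toy <- generate_toy_protein(toy_structure_spec(folded_size = 25,
                                                 n_tail = 15, seed = 9))
  topo <- build_protein_topology(toy$structure, toy$disordered)
  x <- topo$xyz0
  E0 <- potential_energy(x, topo, el)$energy
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3)
  E1 <- potential_energy(x %*% R + 7.3, topo, el)$energy
  expect_equal(E1, E0, tolerance = 1e-9)
})

test_that("complex topology merges protein and DNA with native contacts", {
  toy <- build_toy_structures(toy_structure_spec(folded_size = 30,
                                                 n_tail = 10,
                                                 dna_bp = 10, seed = 4))
  pt <- build_protein_topology(toy$protein$structure,
                               toy$protein$disordered)
  dt <- build_dna_topology(toy$complex$dna)
  ct <- build_complex_topology(pt, dt)
  expect_equal(nrow(ct$beads), nrow(pt$beads) + nrow(dt$beads))
  pd <- ct$pairs[ct$pairs$type == "native_pd", ]
  expect_gt(nrow(pd), 0)
  expect_true(all(pd$j > nrow(pt$beads)))
  expect_equal(unique(pd$sigma), 0.5)
})
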