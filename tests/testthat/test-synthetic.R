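test_that("photon generator closes the loop with burst analysis", {
  spec <- photon_generator_spec(E_true = 0.43, n_bursts = 5000,
                                burst_size_mean = 60, seed = 2)
  g <- generate_photon_stream(spec)
  bursts <- identify_bursts(g$stream, min_photons = 30)
  ob <- burst_observables(g$stream, bursts)
  kept <- filter_bursts(ob, g$stream)
  fit <- fit_histogram(kept$E, components = 1)
  expect_equal(fit$components$mean, 0.43, tolerance = 0.025)
  ## per-burst E is binomial about the true E: variance ~ E(1-E)/n
  nbar <- mean(kept$nDD + kept$nAD)
  expect_equal(stats::var(kept$E), 0.43 * 0.57 / nbar,
               tolerance = 0.25)
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- generate_photon_stream(photon_generator_spec(seed = 5,
                                                     n_bursts = 50))
  s2 <- generate_photon_stream(photon_generator_spec(seed = 5,
                                                     n_bursts = 50))
  expect_identical(s1$stream$time, s2$stream$time)
  t1 <- generate_titration_series("denaturant",
                                  list(E0 = 0.4, dE = 0.6, Ka = 0.3),
                                  noise = 0.01, seed = 3)
  t2 <- generate_titration_series("denaturant",
                                  list(E0 = 0.4, dE = 0.6, Ka = 0.3),
                                  noise = 0.01, seed = 3)
  expect_identical(t1$observable, t2$observable)
  p1 <- generate_toy_protein(toy_structure_spec(seed = 4,
                                                folded_size = 30,
                                                n_tail = 20))
  p2 <- generate_toy_protein(toy_structure_spec(seed = 4,
                                                folded_size = 30,
                                                n_tail = 20))
  expect_identical(p1$structure$xyz, p2$structure$xyz)
})

test_that("noiseless titration series lie exactly on the model curve", {
  p <- list(KD = 1e-6, ddmax = 0.3, P_tot = 3e-5)
  ser <- generate_titration_series("nmr-shift", p, n = 8, noise = 0)
  expect_equal(ser$observable,
               shift_titration_model(ser$concentration, p$KD, p$ddmax,
                                     p$P_tot))
  ser0 <- generate_titration_series("nmr-shift",
                                    list(KD = 1e-6, ddmax = 0,
                                         P_tot = 3e-5), n = 6,
                                    noise = 0)
  expect_true(all(ser0$observable == 0))
})

test_that("toy protein realises the requested architecture", {
  spec <- toy_structure_spec(folded_size = 80, n_tail = 195,
                             folded_charge = 13, tail_charges = 9,
                             seed = 6)
  toy <- generate_toy_protein(spec)
  n <- 80 + 195
  expect_equal(nrow(toy$structure$xyz), n)
  ## tail contour length = n_tail bonds of ~bond_length
  i_tail <- toy$disordered$ctail
  expect_equal(length(i_tail), 195)
  bd <- sqrt(rowSums(diff(toy$structure$xyz)^2))
  expect_true(all(bd < 0.6))
  ## charges: +13 net in the fold, zero net with 18 charged in the tail
  ch <- cgfret:::.aa_charge(toy$sequence)
  expect_equal(sum(ch[setdiff(seq_len(n), i_tail)]), 13)
  expect_equal(sum(ch[i_tail]), 0)
  expect_equal(sum(ch[i_tail] != 0), 18)
})

test_that("generated duplex has B-form pitch and docks with a native contact", {
  dna <- generate_dna_duplex(147, seed = 2)
  ## helical pitch: base beads of strand A advance 34.3 deg per bp
  iN1 <- which(dna$atom == "N1" & dna$chain == "A")
  xy <- dna$xyz[iN1, 1:2]
  ang <- atan2(xy[, 2], xy[, 1])
  dphi <- diff(ang) %% (2 * pi)
  dphi[dphi > pi] <- dphi[dphi > pi] - 2 * pi
  pitch_bp <- 2 * pi / mean(abs(dphi))
  expect_equal(pitch_bp, 10.5, tolerance = 0.01)
  ## rise 0.34 nm
  expect_equal(mean(diff(dna$xyz[iN1, 3])), 0.34, tolerance = 1e-6)
  ## docked complex has at least one contact below 0.5 nm
  toy <- build_toy_structures(toy_structure_spec(folded_size = 40,
                                                 n_tail = 20,
                                                 dna_bp = 20, seed = 3))
  pd <- detect_native_contacts(toy$complex$protein$structure,
                               toy$complex$dna,
                               domain = "protein-dna")
  expect_gte(nrow(pd), 1)
})

test_that("PDB round trip preserves the CG structure", {
  toy <- generate_toy_protein(toy_structure_spec(folded_size = 20,
                                                 n_tail = 10, seed = 8))
  f <- tempfile(fileext = ".pdb")
  write_cg_pdb(toy$structure, f)
  back <- read_cg_pdb(f, kind = "protein")
  expect_equal(back$xyz, toy$structure$xyz, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(back$restype, toy$structure$restype)
  unlink(f)
  dna <- generate_dna_duplex(10, seed = 9)
  fd <- tempfile(fileext = ".pdb")
  write_cg_pdb(dna, fd)
  dback <- read_cg_pdb(fd, kind = "dna")
  expect_equal(nrow(dback$xyz), nrow(dna$xyz))
  expect_equal(dback$atom, dna$atom)
  unlink(fd)
})
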