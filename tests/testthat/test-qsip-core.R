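test_that("fraction filter enforces the density window and read floor", {
  qd <- toy_tube_data(
    densities = c(1.60, 1.614, 1.70, 1.753, 1.76),
    total_copies = rep(1e6, 5),
    total_read_pairs = c(5000, 5000, 2000, 5000, 5000),
    reads = matrix(10, 2, 5)
  )
  filt <- filter_fractions(qd)
  kept <- filt$fractions
  # 1.60 and 1.76 outside the window; boundaries are inclusive;
  # exactly 2000 read pairs fails the strict > rule
  expect_equal(kept$density, c(1.614, 1.753))
  expect_equal(nrow(filt$counts), 4)
  ret <- attr(filt, "retained_fractions")
  expect_true(ret$flagged_few[ret$tube_id == "tube1"])
})

test_that("filter is the identity on clean in-window data", {
  qd <- toy_tube_data(
    densities = seq(1.62, 1.75, length.out = 6),
    total_copies = rep(1e6, 6), total_read_pairs = rep(9000, 6),
    reads = matrix(5, 3, 6)
  )
  filt <- filter_fractions(qd)
  expect_equal(filt$fractions, qd$fractions)
  expect_equal(filt$counts, qd$counts)
})

test_that("taxon WADs are copy-weighted mean densities", {
  # symmetric weights: WAD is the middle density
  qd <- toy_tube_data(
    densities = c(1.70, 1.71, 1.72), total_copies = rep(100, 3),
    total_read_pairs = rep(9000, 3),
    reads = rbind(c(10, 80, 10), c(5, 5, 5))
  )
  w <- taxon_wads(qd)
  expect_equal(w$wad[w$taxon_id == "t1"], 1.71)
  expect_equal(w$n_fractions_present[w$taxon_id == "t1"], 3)
  # single-fraction taxon sits at that fraction's density
  qd2 <- toy_tube_data(
    densities = c(1.70, 1.71), total_copies = c(100, 100),
    total_read_pairs = rep(9000, 2),
    reads = rbind(c(0, 7), c(3, 3))
  )
  w2 <- taxon_wads(qd2)
  expect_equal(w2$wad[w2$taxon_id == "t1"], 1.71)
})

test_that("taxon WADs match the brute-force weighted-mean oracle", {
  set.seed(99)
  for (i in 1:25) {
    n_f <- 8
    reads <- matrix(rpois(3 * n_f, 40), 3, n_f)
    total_copies <- runif(n_f, 1e5, 1e7)
    densities <- sort(runif(n_f, 1.62, 1.75))
    qd <- toy_tube_data(densities, total_copies, rep(9000, n_f), reads)
    w <- taxon_wads(qd)
    for (tx in 1:3) {
      copies <- reads[tx, ] / colSums(reads) * total_copies
      expect_equal(w$wad[w$taxon_id == paste0("t", tx)],
                   oracle_wad(densities, copies), tolerance = 1e-12)
    }
  }
})

test_that("taxa absent from a tube have no WAD row rather than zero", {
  qd <- toy_tube_data(
    densities = c(1.70, 1.71), total_copies = c(100, 100),
    total_read_pairs = rep(9000, 2),
    reads = rbind(c(0, 0), c(3, 3))
  )
  w <- taxon_wads(qd)
  expect_false("t1" %in% w$taxon_id)
})

test_that("prevalence filter applies the fraction and replicate rules", {
  # five taxa with designed presence patterns across 2 labeled tubes:
  # t1: 4 fractions in both tubes          -> retained (boundary)
  # t2: 10 fractions in tube A only        -> removed (one replicate)
  # t3: 3 fractions in both                -> removed (too few fractions)
  # t4: 5 in A, 4 in B                     -> retained
  # t5: absent                             -> removed
  n_f <- 10
  mk_reads <- function(pattern) {
    m <- matrix(0, 5, n_f)
    for (i in seq_along(pattern)) m[i, seq_len(pattern[i])] <- 1
    m
  }
  tubes <- list(
    toy_tube_data(seq(1.62, 1.75, length.out = n_f), rep(1e6, n_f),
                  rep(9000, n_f), mk_reads(c(4, 10, 3, 5, 0)),
                  tube_id = "A"),
    toy_tube_data(seq(1.62, 1.75, length.out = n_f), rep(1e6, n_f),
                  rep(9000, n_f), mk_reads(c(4, 0, 3, 4, 0)),
                  tube_id = "B", replicate = 2)
  )
  qd <- qsip_data(
    dplyr::bind_rows(tubes[[1]]$counts, tubes[[2]]$counts),
    dplyr::bind_rows(tubes[[1]]$fractions, tubes[[2]]$fractions),
    dplyr::bind_rows(tubes[[1]]$samples, tubes[[2]]$samples),
    tubes[[1]]$taxonomy
  )
  kept <- prevalence_filter(qd)
  expect_setequal(kept$taxon_id, c("t1", "t4"))
  cov <- attr(kept, "coverage")
  expect_true(cov$coverage > 0 && cov$coverage < 1)
})

test_that("GC inference inverts the linear density relation with clamping", {
  expect_equal(gc_from_wad(1.646057), 0)
  expect_equal(gc_from_wad(1.646057 + 0.083506), 1)
  expect_equal(gc_from_wad(1.687810), 0.5, tolerance = 1e-6)
  expect_warning(out <- gc_from_wad(c(1.60, 1.75)), "clamped")
  expect_equal(out, c(0, 1))
})

test_that("molecular weights follow the GC relations with a constant shift", {
  mw <- molecular_weights(c(0, 0.5, 1))
  expect_equal(mw$m_light, c(307.691, 307.939, 308.187))
  expect_equal(mw$m_heavymax - mw$m_light, rep(12.07747, 3))
  expect_error(molecular_weights(1.2), "0, 1")
})

test_that("excess atom fraction is the exact inverse of the density shift", {
  cs <- qsip_constants()
  for (gc in c(0, 0.25, 0.5, 0.75, 1)) {
    w_light <- cs$density_gc_intercept + cs$density_gc_slope * gc
    eafs <- seq(0, 1 - cs$nat_abund_18O, length.out = 41)
    w_lab <- wad_shift_from_eaf(gc, w_light, eafs)
    back <- excess_atom_fraction(w_light, w_lab)
    expect_equal(back, eafs, tolerance = 1e-12)
  }
  expect_equal(excess_atom_fraction(1.687810, 1.687810), 0)
  # saturation: labeled weight at its maximum gives EAF = 1 - natural abundance
  mw <- molecular_weights(0.5)
  w_sat <- 1.687810 * mw$m_heavymax / mw$m_light
  expect_equal(excess_atom_fraction(1.687810, w_sat), 0.997999571)
})

test_that("EAF increases strictly with the labeled density", {
  w_lab <- seq(1.69, 1.75, length.out = 50)
  eaf <- excess_atom_fraction(1.687810, w_lab)
  expect_true(all(diff(eaf) > 0))
})

test_that("EAF is invariant to uniform read and ddPCR rescaling in a tube", {
  sim <- small_sim()
  filt <- filter_fractions(sim$data)
  base <- enrich_all(filt)
  scaled <- filt
  scaled$counts$reads <- scaled$counts$reads * 7
  scaled$fractions$total_copies <- scaled$fractions$total_copies * 0.13
  again <- enrich_all(scaled)
  expect_equal(base$eaf, again$eaf, tolerance = 1e-12)
})

test_that("WAD offset correction recenters tubes with lost fractions", {
  des <- qsip_design(scenarios = "ambient", n_taxa = 60, replicates = 3,
                     reads_per_tube = 30000, seed = 77,
                     drop_lightest = c(ambient_r1_18O = 3))
  sim <- simulate_experiment(des)
  filt <- filter_fractions(sim$data)
  cw_before <- community_wads(filt)
  corr <- correct_wad_offset(filt, "ambient_r1_18O")
  off <- attr(corr, "offsets")
  expect_gt(off$offset, 0) # lost light fractions bias the tube heavy
  cw_after <- community_wads(corr)
  refs <- cw_after$community_wad[cw_after$tube_id %in%
                                   c("ambient_r2_18O", "ambient_r3_18O")]
  fixed <- cw_after$community_wad[cw_after$tube_id == "ambient_r1_18O"]
  expect_lt(abs(fixed - mean(refs)), 0.002)
  # unflagged tubes untouched
  expect_equal(cw_after$community_wad[cw_after$tube_id == "ambient_r2_18O"],
               cw_before$community_wad[cw_before$tube_id == "ambient_r2_18O"])
})

test_that("offset correction is a no-op for a tube matching its references", {
  sim <- small_sim()
  filt <- filter_fractions(sim$data)
  corr <- correct_wad_offset(filt, "ambient_r1_18O")
  off <- attr(corr, "offsets")
  expect_lt(abs(off$offset), 0.002) # only sampling noise
  expect_error(
    correct_wad_offset(filt, c("ambient_r1_18O", "ambient_r2_18O",
                               "ambient_r3_18O")),
    "uncorrectable"
  )
})

test_that("an unenriched experiment yields near-zero APE and no growers", {
  des <- qsip_design(scenarios = c(none_a = 0, none_b = 0), n_taxa = 40,
                     replicates = 2, reads_per_tube = 30000, seed = 19)
  sim <- simulate_experiment(des)
  enr <- enrich_all(filter_fractions(sim$data))
  expect_equal(sum(enr$growing), 0)
  expect_lt(median(abs(enr$ape)), 1)
})

test_that("activity thresholds partition taxa into inactive/active/growing", {
  sim <- small_sim()
  enr <- enrich_all(filter_fractions(sim$data))
  expect_true(all(enr$growing == (enr$ape > 5)))
  expect_true(all(enr$active == (enr$ape > 0)))
  expect_true(all(enr$eaf[enr$growing] > 0.05))
  expect_true(sum(enr$active) >= sum(enr$growing))
  # collapsing the growing threshold onto the active one merges the classes
  enr0 <- enrich_all(filter_fractions(sim$data), ape_growing_threshold = 0)
  expect_equal(enr0$growing, enr0$active)
})

test_that("unlabeled reference falls back from treatment to global mean", {
  n_f <- 8
  dens <- seq(1.66, 1.72, length.out = n_f)
  reads_with <- matrix(10, 2, n_f)
  reads_without <- rbind(rep(10, n_f), rep(0, n_f)) # t2 missing
  mk <- function(tube, iso, trt, rep_, reads) {
    toy_tube_data(dens, rep(1e6, n_f), rep(9000, n_f), reads,
                  tube_id = tube, isotope = iso, treatment = trt,
                  replicate = rep_)
  }
  pieces <- list(
    mk("L1", "18O", "amb", 1, reads_with),
    mk("L2", "18O", "amb", 2, reads_with),
    mk("U1", "16O", "amb", 1, reads_without),
    mk("L3", "18O", "oth", 1, reads_with),
    mk("L4", "18O", "oth", 2, reads_with),
    mk("U2", "16O", "oth", 1, reads_with)
  )
  qd <- qsip_data(
    dplyr::bind_rows(purrr::map(pieces, "counts")),
    dplyr::bind_rows(purrr::map(pieces, "fractions")),
    dplyr::bind_rows(purrr::map(pieces, "samples")),
    pieces[[1]]$taxonomy
  )
  enr <- enrich_all(qd)
  # t2 has no unlabeled WAD in "amb": its reference must come from U2 (global)
  t2_amb <- enr[enr$taxon_id == "t2" & enr$treatment == "amb", ]
  expect_equal(nrow(t2_amb), 2)
  w_u2 <- taxon_wads(qd)
  ref <- w_u2$wad[w_u2$tube_id == "U2" & w_u2$taxon_id == "t2"]
  expect_equal(unique(t2_amb$w_light), ref)
})
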