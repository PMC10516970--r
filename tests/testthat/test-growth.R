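test_that("relative growth rate scales APE by water label and time", {
  expect_equal(relative_growth_rate(29.65, 59.3, 5), 0.1)
  expect_equal(relative_growth_rate(0, 59.3, 5), 0)
  # a fully labeled taxon over 5 days grows at 0.2/day
  expect_equal(relative_growth_rate(59.3, 59.3, 5), 0.2)
  expect_error(relative_growth_rate(10, 0, 5), "invalid label")
  expect_error(relative_growth_rate(10, 59.3, 0), "days")
})

test_that("absolute abundances distribute ddPCR totals by read share", {
  # one taxon takes everything
  qd <- toy_tube_data(c(1.70, 1.71), c(4e8, 6e8), c(9000, 9000),
                      rbind(c(10, 20), c(0, 0)))
  ab <- absolute_abundances(qd)
  expect_equal(ab$copies[ab$taxon_id == "t1"], 1e9)
  # 30/70 split of 1e9 copies
  qd2 <- toy_tube_data(c(1.70, 1.71), c(4e8, 6e8), c(9000, 9000),
                       rbind(c(10, 20), c(30, 40)))
  ab2 <- absolute_abundances(qd2)
  expect_equal(ab2$copies[ab2$taxon_id == "t1"], 0.3e9)
  expect_equal(ab2$copies[ab2$taxon_id == "t2"], 0.7e9)
})

test_that("absolute abundances match the brute-force two-step oracle", {
  set.seed(7)
  for (i in 1:20) {
    n_f <- 6
    reads <- matrix(rpois(4 * n_f, 30), 4, n_f)
    total_copies <- runif(n_f, 1e5, 1e7)
    qd <- toy_tube_data(seq(1.65, 1.74, length.out = n_f), total_copies,
                        rep(9000, n_f), reads,
                        taxon_ids = paste0("t", 1:4))
    ab <- absolute_abundances(qd)
    expected <- oracle_absolute_abundance(reads, total_copies)
    expect_equal(ab$copies[match(paste0("t", 1:4), ab$taxon_id)],
                 unname(expected), tolerance = 1e-9)
  }
})

test_that("growing fraction is the copy share of flagged taxa", {
  ab <- tibble::tibble(tube_id = "s1", taxon_id = c("a", "b", "c"),
                       rel_abund = c(0.35, 0.35, 0.3),
                       copies = c(35, 35, 30), total_copies = 100)
  enr <- tibble::tibble(tube_id = "s1", taxon_id = c("a", "b", "c"),
                        growing = c(TRUE, FALSE, FALSE))
  expect_equal(growing_fraction(ab, enr)$growing_pct, 35)
  enr$growing <- FALSE
  expect_equal(growing_fraction(ab, enr)$growing_pct, 0)
  enr$growing <- TRUE
  expect_equal(growing_fraction(ab, enr)$growing_pct, 100)
})

test_that("proportional assimilation reweights abundance by growth rate", {
  mk_enr <- function(rgr, ids = c("a", "b")) {
    tibble::tibble(
      tube_id = "s1", treatment = "amb", taxon_id = ids, growing = TRUE,
      ape = rgr * 59.3 * 5 / 100 * 100, soil_water_ape = 59.3,
      incubation_days = 5
    )
  }
  ab <- tibble::tibble(tube_id = "s1", taxon_id = c("a", "b"),
                       copies = c(50, 50))
  pa <- proportional_assimilation(ab, mk_enr(c(0.1, 0.3)))
  expect_equal(sort(pa$proportional_assimilation), c(0.25, 0.75))
  # single growing taxon takes it all
  ab1 <- ab[1, ]
  pa1 <- proportional_assimilation(ab1, mk_enr(0.1, "a")[1, ])
  expect_equal(pa1$proportional_assimilation, 1)
  # equal rates: contribution reduces to relative abundance
  ab3 <- tibble::tibble(tube_id = "s1", taxon_id = c("a", "b"),
                        copies = c(20, 80))
  pa3 <- proportional_assimilation(ab3, mk_enr(c(0.2, 0.2)))
  expect_equal(pa3$proportional_assimilation[order(pa3$taxon_id)], c(0.2, 0.8))
  # invariant to rescaling the abundances
  ab3$copies <- ab3$copies * 1e6
  pa4 <- proportional_assimilation(ab3, mk_enr(c(0.2, 0.2)))
  expect_equal(pa4$proportional_assimilation, pa3$proportional_assimilation)
  # all-zero rates are undefined
  expect_error(proportional_assimilation(ab, mk_enr(c(0, 0))), "undefined")
})

test_that("assimilation sums to one within each sample of a simulation", {
  sim <- small_sim()
  filt <- filter_fractions(sim$data)
  enr <- enrich_all(filt)
  pa <- proportional_assimilation(absolute_abundances(filt), enr)
  sums <- tapply(pa$proportional_assimilation, pa$tube_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("top assimilators honour ranking, eligibility and label fallback", {
  # 4 samples, 2 treatments; taxa p/q/r/s/u with designed contributions
  rec <- tidyr::expand_grid(
    tube_id = c("s1", "s2", "s3", "s4"),
    taxon_id = c("p", "q", "r", "s", "u")
  )
  rec$treatment <- ifelse(rec$tube_id %in% c("s1", "s2"), "amb", "dro")
  val <- c(
    s1 = c(p = 0.5, q = 0.3, r = 0.1, s = 0.07, u = 0.03),
    s2 = c(p = 0.6, q = 0.2, r = 0.1, s = 0.06, u = 0.04),
    s3 = c(p = 0.1, q = 0.1, r = 0.5, s = 0.2, u = 0.1),
    s4 = c(p = 0.2, q = 0.1, r = 0.4, s = 0.2, u = 0.1)
  )
  rec$proportional_assimilation <- val[paste0(rec$tube_id, ".", rec$taxon_id)]
  rec$rel_abund_growing <- 0.2
  rec$rgr <- 0.1
  rec$rank <- NA
  taxonomy <- tibble::tibble(
    taxon_id = c("p", "q", "r", "s", "u"),
    domain = "Bacteria",
    phylum = c("Actinobacteriota", "Proteobacteria", "Acidobacteriota",
               "Bacteroidota", "Planctomycetota"),
    class = NA, order = NA,
    family = c("Streptomycetaceae", NA, "F3", "env.OPS 17", NA),
    genus = c("Streptomyces", NA, NA, NA, NA),
    species = NA
  )
  # top 2 per sample: all five taxa are eligible (present in 2 samples of
  # their treatment); union of top-2 = {p, q} (amb) + {r, s} (dro)
  top <- top_assimilators(rec, taxonomy, n = 2, min_samples = 2)
  expect_setequal(unique(top$taxon_id), c("p", "q", "r", "s"))
  expect_true(all(top$rank <= 2))
  # labels: genus where assigned, else family, else phylum
  expect_equal(unique(top$label[top$taxon_id == "p"]), "Streptomyces")
  expect_equal(unique(top$label_rank[top$taxon_id == "q"]), "phylum")
  expect_equal(unique(top$label[top$taxon_id == "s"]), "env.OPS 17")
  # n larger than the number of taxa returns everything eligible
  all5 <- top_assimilators(rec, taxonomy, n = 10, min_samples = 2)
  expect_setequal(unique(all5$taxon_id), c("p", "q", "r", "s", "u"))
})

test_that("treatment overlap computes Venn regions and shared counts", {
  ov <- treatment_overlap(list(A = c("x", "y", "z"), B = c("y", "z", "w")))
  expect_equal(ov$shared["A", "B"], 2)
  expect_equal(unname(ov$unique_counts), c(1, 1))
  expect_equal(sum(ov$regions$n), 4) # regions partition the union
  # disjoint sets share nothing
  ov2 <- treatment_overlap(list(A = c("a", "b"), B = c("c"), C = c("d")))
  expect_true(all(ov2$shared[upper.tri(ov2$shared)] == 0))
  # identical sets: everything shared, nothing unique
  ov3 <- treatment_overlap(list(A = c("a", "b"), B = c("a", "b")))
  expect_equal(ov3$shared["A", "B"], 2)
  expect_equal(unname(ov3$unique_counts), c(0, 0))
  expect_error(treatment_overlap(list(c("a"), c("b"))), "named")
})

test_that("overlap_with_any counts taxa shared with any reference set", {
  sets <- list(A = c("1", "2", "3"), D = c("2", "9"), F2 = c("3", "9"))
  ov <- treatment_overlap(sets)
  expect_equal(overlap_with_any(ov, "D", c("A", "F2")), 2) # "2" and "9"
  expect_error(overlap_with_any(ov, "D", "nope"), "unknown")
})

test_that("growing sets demand the replicate-consistency rule", {
  enr <- tibble::tibble(
    treatment = rep("amb", 5),
    tube_id = c("s1", "s2", "s1", "s2", "s1"),
    taxon_id = c("a", "a", "b", "b", "c"),
    growing = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  gs <- growing_sets(enr, min_replicates = 2)
  expect_equal(gs$amb, "a")
  gs1 <- growing_sets(enr, min_replicates = 1)
  expect_setequal(gs1$amb, c("a", "b", "c"))
})

test_that("phylum change is relative to the reference treatment mean", {
  gc <- tidyr::expand_grid(tube_id = paste0("s", 1:8), phylum = c("P1", "P2"))
  gc$treatment <- ifelse(gc$tube_id %in% paste0("s", 1:4), "ref", "dro")
  gc$n_growing <- ifelse(gc$phylum == "P1",
                         ifelse(gc$treatment == "ref", 10, 10.7),
                         ifelse(gc$treatment == "ref", 10, 5))
  ch <- phylum_change(gc, reference = "ref")
  expect_equal(ch$rel_change[ch$phylum == "P1"], 0.07)
  expect_equal(ch$rel_change[ch$phylum == "P2"], -0.5)
  # zero reference mean flags rather than crashes
  gc$n_growing[gc$phylum == "P2" & gc$treatment == "ref"] <- 0
  ch2 <- phylum_change(gc, reference = "ref")
  expect_true(ch2$undefined[ch2$phylum == "P2"])
  expect_true(is.na(ch2$rel_change[ch2$phylum == "P2"]))
  # identical means change nothing
  gc$n_growing <- 3
  ch3 <- phylum_change(gc, reference = "ref")
  expect_true(all(ch3$rel_change == 0))
  expect_error(phylum_change(gc, reference = "missing"), "no samples")
})

test_that("putative predators are flagged by their order", {
  expect_true(flag_putative_predators("Myxococcales"))
  expect_true(flag_putative_predators("bdellovibrionales"))
  expect_equal(
    flag_putative_predators(c("Haliangiales", "Polyangiales",
                              "Vampirovibrionales", "Rhizobiales", NA)),
    c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
})

test_that("sample mean growth rates follow the clamping conventions", {
  enr <- tibble::tibble(
    tube_id = "s1", treatment = "amb",
    taxon_id = c("a", "b", "c", "d"),
    ape = c(29.65, 88.95, 2, -3), eaf = c(0.2965, 0.8895, 0.02, -0.03),
    growing = c(TRUE, TRUE, FALSE, FALSE),
    soil_water_ape = 59.3, incubation_days = 5
  )
  g <- sample_mean_rgr(enr, include_nongrowing = FALSE)
  expect_equal(g$mean_rgr, 0.2) # mean of 0.1 and 0.3
  a <- sample_mean_rgr(enr, include_nongrowing = TRUE)
  # negative enrichment clamps to zero growth, not negative growth
  expect_equal(a$mean_rgr,
               mean(c(0.1, 0.3, relative_growth_rate(2, 59.3, 5), 0)))
  expect_lte(a$mean_rgr, g$mean_rgr)
})

test_that("all-taxa mean RGR never exceeds the growing-only mean", {
  sim <- small_sim()
  enr <- enrich_all(filter_fractions(sim$data))
  g <- sample_mean_rgr(enr, include_nongrowing = FALSE)
  a <- sample_mean_rgr(enr, include_nongrowing = TRUE)
  m <- dplyr::inner_join(g, a, by = c("tube_id", "treatment"),
                         suffix = c("_g", "_a"))
  ok <- !is.na(m$mean_rgr_g)
  expect_true(all(m$mean_rgr_a[ok] <= m$mean_rgr_g[ok]))
  # growing-only mean equals a brute-force mean over flagged taxa
  s <- enr$tube_id[1]
  sub <- enr[enr$tube_id == s & enr$growing, ]
  expect_equal(g$mean_rgr[g$tube_id == s],
               mean(sub$ape / 100 / (sub$soil_water_ape / 100 * sub$incubation_days)))
})
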