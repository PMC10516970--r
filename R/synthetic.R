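# Synthetic vapor-qSIP experiments with known ground truth.
#
# The generator emulates the structure of a vapor-qSIP study: a full
# factorial drought x climate design, one labeled (18O) and one
# natural-abundance (16O) tube per replicate plot, 24 gradient fractions per
# tube, amplicon reads per fraction and ddPCR totals per fraction. Every
# taxon carries a known GC content, abundance and true 18O excess atom
# fraction, so estimator output can be scored against truth.

#' Noise model of the synthetic gradient generator
#'
#' @param reads `"multinomial"` (reads drawn multinomially from per-cell copy
#'   proportions) or `"expected"` (deterministic expected reads, possibly
#'   fractional — the noiseless limit).
#' @param ddpcr_sdlog lognormal sd of the ddPCR total-copy measurement per
#'   fraction (0 = exact).
#' @param density_sd Gaussian sd (g/mL) of the refractometer density reading.
#' @param wlight_sd taxon-level sd (g/mL) around the linear density-GC
#'   relation, making GC inference imperfect as in real gradients.
#' @param tube_abund_sdlog lognormal sd of a taxon's abundance across tubes
#'   (biological replicate variation).
#' @return A named list of class `qsip_noise`.
#' @examples
#' qsip_noise()
#' qsip_noise_off()
#' @export
qsip_noise <- function(reads = c("multinomial", "expected"),
                       ddpcr_sdlog = 0.1,
                       density_sd = 0.0005,
                       wlight_sd = 0.002,
                       tube_abund_sdlog = 0.25) {
  reads <- match.arg(reads)
  stopifnot(ddpcr_sdlog >= 0, density_sd >= 0, wlight_sd >= 0,
            tube_abund_sdlog >= 0)
  structure(
    list(reads = reads, ddpcr_sdlog = ddpcr_sdlog, density_sd = density_sd,
         wlight_sd = wlight_sd, tube_abund_sdlog = tube_abund_sdlog),
    class = "qsip_noise"
  )
}

#' @rdname qsip_noise
#' @export
qsip_noise_off <- function() {
  qsip_noise(reads = "expected", ddpcr_sdlog = 0, density_sd = 0,
             wlight_sd = 0, tube_abund_sdlog = 0)
}

#' Design of a synthetic vapor-qSIP experiment
#'
#' Defaults mirror the study conditions the generator emulates: a 2x2
#' drought x climate factorial, one labeled plus one natural-abundance tube
#' per replicate, 24 fractions of the CsCl gradient spanning 1.60-1.78 g/mL,
#' a 5-day incubation, and per-treatment time-averaged soil-water enrichments
#' drawn between 55 and 64 atom% excess.
#'
#' @param scenarios character or numeric vector, one element per treatment.
#'   Character entries name growing-share presets (`"ambient"` = 35% of
#'   community 16S copies in growing taxa, `"drought"` = 4%, `"future"` =
#'   45%, `"future_drought"` = 9%); numeric entries give the share directly
#'   (0-1). Names give treatment labels (defaults to the preset names).
#' @param n_taxa number of taxa (>= 10).
#' @param replicates replicate plots per treatment (>= 2; each contributes a
#'   labeled and an unlabeled tube).
#' @param n_fractions gradient fractions per tube (>= 4).
#' @param density_range range (g/mL) spanned by the fraction grid.
#' @param reads_per_tube total amplicon read pairs per tube.
#' @param incubation_days length of the labeling incubation (days).
#' @param soil_water_ape per-treatment time-averaged soil-water enrichment
#'   (atom % excess); `NULL` draws one value per treatment uniformly in
#'   55-64.
#' @param sigma_d within-tube density spread of a taxon's DNA (g/mL);
#'   default 0.006 spreads DNA over ~4-6 fractions.
#' @param pcr_saturation half-saturation constant of per-fraction library
#'   yield, as a share of the tube's total DNA. Amplicon libraries are
#'   prepared per fraction with a fixed cycle number, so sequencing depth
#'   saturates once a fraction holds appreciable template instead of scaling
#'   with DNA mass; fractions holding much less template than this share
#'   yield proportionally fewer reads. Within-fraction composition remains
#'   proportional to template copies.
#' @param noise a [qsip_noise()] model.
#' @param drop_lightest optional named integer vector: for each named tube id
#'   drop that many of its lightest fractions (emulates fraction loss during
#'   gradient collection, exercising the WAD offset correction).
#' @param seed master seed; per-tube seeds are derived from it by hashing
#'   tube ids, so the output is fully reproducible.
#' @return A list of class `qsip_design`.
#' @examples
#' qsip_design(n_taxa = 50, replicates = 2, reads_per_tube = 5000, seed = 1)
#' @export
qsip_design <- function(scenarios = c("ambient", "drought", "future", "future_drought"),
                        n_taxa = 200,
                        replicates = 4,
                        n_fractions = 24,
                        density_range = c(1.60, 1.78),
                        reads_per_tube = 50000,
                        incubation_days = 5,
                        soil_water_ape = NULL,
                        sigma_d = 0.006,
                        pcr_saturation = 0.005,
                        noise = qsip_noise(),
                        drop_lightest = NULL,
                        seed = 1L) {
  if (n_taxa < 10) abort("`n_taxa` must be >= 10")
  if (replicates < 2) abort("`replicates` must be >= 2 (the prevalence filter needs 2)")
  if (n_fractions < 4) abort("`n_fractions` must be >= 4")
  stopifnot(length(density_range) == 2, diff(density_range) > 0)
  trt <- names(scenarios) %||% as.character(scenarios)
  if (is.null(names(scenarios)) && is.numeric(scenarios)) {
    trt <- paste0("treatment", seq_along(scenarios))
  }
  if (anyDuplicated(trt)) abort("treatment names must be unique")
  if (!is.null(soil_water_ape) && length(soil_water_ape) != length(scenarios)) {
    abort("`soil_water_ape` must have one value per treatment")
  }
  treatments <- tibble::tibble(
    treatment = trt,
    scenario = unname(scenarios),
    drought = ifelse(grepl("drought", trt), "yes", "no"),
    climate = ifelse(grepl("future", trt), "future", "ambient")
  )
  structure(
    list(treatments = treatments, n_taxa = n_taxa, replicates = replicates,
         n_fractions = n_fractions, density_range = density_range,
         reads_per_tube = reads_per_tube, incubation_days = incubation_days,
         soil_water_ape = soil_water_ape, sigma_d = sigma_d,
         pcr_saturation = pcr_saturation, noise = noise,
         drop_lightest = drop_lightest, seed = as.integer(seed)),
    class = "qsip_design"
  )
}

scenario_growing_share <- function(scenario) {
  if (is.numeric(scenario)) {
    if (scenario < 0 || scenario > 1) abort("numeric scenario must be a share in [0, 1]")
    return(as.numeric(scenario))
  }
  presets <- c(ambient = 0.35, drought = 0.04, future = 0.45,
               future_drought = 0.09)
  share <- presets[as.character(scenario)]
  if (is.na(share)) {
    abort(sprintf(
      "unknown scenario '%s'; use one of %s or a numeric share",
      scenario, paste(names(presets), collapse = ", ")
    ))
  }
  unname(share)
}

# Small synthetic taxonomy pool. Includes predator orders and unassigned
# genera so downstream label logic gets exercised; names are real lineages
# but assignment to taxa is random.
synthetic_lineages <- function() {
  tribble <- tibble::tribble(
    ~domain, ~phylum, ~class, ~order, ~family, ~genus,
    "Bacteria", "Actinobacteriota", "Actinobacteria", "Streptomycetales", "Streptomycetaceae", "Streptomyces",
    "Bacteria", "Actinobacteriota", "Actinobacteria", "Propionibacteriales", "Nocardioidaceae", "Marmoricola",
    "Bacteria", "Actinobacteriota", "Actinobacteria", "Corynebacteriales", "Nocardiaceae", "Rhodococcus",
    "Bacteria", "Actinobacteriota", "Actinobacteria", "Micrococcales", "Intrasporangiaceae", "Oryzihumus",
    "Bacteria", "Actinobacteriota", "Thermoleophilia", "Solirubrobacterales", "Solirubrobacteraceae", NA,
    "Bacteria", "Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Xanthobacteraceae", "Bradyrhizobium",
    "Bacteria", "Proteobacteria", "Gammaproteobacteria", "Burkholderiales", "Oxalobacteraceae", "Pseudoduganella",
    "Bacteria", "Proteobacteria", "Gammaproteobacteria", "Burkholderiales", "Comamonadaceae", NA,
    "Bacteria", "Proteobacteria", "Alphaproteobacteria", "Sphingomonadales", "Sphingomonadaceae", "Sphingomonas",
    "Bacteria", "Myxococcota", "Myxococcia", "Myxococcales", "Myxococcaceae", "Corallococcus",
    "Bacteria", "Myxococcota", "Polyangia", "Haliangiales", "Haliangiaceae", "Haliangium",
    "Bacteria", "Myxococcota", "Polyangia", "Polyangiales", "Polyangiaceae", NA,
    "Bacteria", "Bdellovibrionota", "Bdellovibrionia", "Bdellovibrionales", "Bdellovibrionaceae", "Bdellovibrio",
    "Bacteria", "Acidobacteriota", "Vicinamibacteria", "Vicinamibacterales", "Vicinamibacteraceae", NA,
    "Bacteria", "Acidobacteriota", "Blastocatellia", "Pyrinomonadales", "Pyrinomonadaceae", "RB41",
    "Bacteria", "Bacteroidota", "Bacteroidia", "Sphingobacteriales", "env.OPS 17", NA,
    "Bacteria", "Bacteroidota", "Bacteroidia", "Chitinophagales", "Chitinophagaceae", "Flavisolibacter",
    "Bacteria", "Planctomycetota", "Planctomycetes", "Pirellulales", "Pirellulaceae", NA,
    "Bacteria", "Verrucomicrobiota", "Verrucomicrobiae", "Chthoniobacterales", "Chthoniobacteraceae", "Chthoniobacter",
    "Bacteria", "Latescibacterota", "Latescibacteria", NA, NA, NA,
    "Archaea", "Crenarchaeota", "Nitrososphaeria", "Nitrososphaerales", "Nitrososphaeraceae", NA
  )
  tribble
}

# Base community: identities, lineages, GC, unlabeled WAD, abundances.
simulate_taxa_base <- function(n_taxa, seed, wlight_sd = 0.002,
                               constants = qsip_constants()) {
  set.seed(seed)
  pool <- synthetic_lineages()
  idx <- sample.int(nrow(pool), n_taxa, replace = TRUE)
  gc <- runif(n_taxa, 0.3, 0.7)
  base <- tibble::tibble(
    taxon_id = sprintf("ASV_%04d", seq_len(n_taxa)),
    pool[idx, ],
    species = NA_character_,
    gc = gc,
    w_light = constants$density_gc_intercept + constants$density_gc_slope * gc +
      rnorm(n_taxa, 0, wlight_sd),
    base_abundance = rlnorm(n_taxa, meanlog = log(1e6), sdlog = 1.5)
  )
  base
}

# Choose a growing set whose abundance-weighted share of community 16S copies
# matches `share`, then draw each growing taxon's true EAF. Growing taxa draw
# EAF from a Beta(2, 4) rescaled onto (0.05, min(afe_water, 1 - nat)): above
# the APE > 5% growing threshold and at most as enriched as the soil water.
# Non-growing taxa do not replicate DNA and have EAF exactly 0.
assign_growth <- function(base, share, afe_water, seed,
                          constants = qsip_constants()) {
  set.seed(seed)
  n <- nrow(base)
  w <- base$base_abundance / sum(base$base_abundance)
  growing <- rep(FALSE, n)
  if (share > 0) {
    ord <- sample.int(n)
    cum <- cumsum(w[ord])
    k <- findInterval(share, cum) # taxa fully below the target share
    growing[ord[seq_len(k)]] <- TRUE
    if (k < n && abs(cum[k + 1] - share) < abs(sum(w[growing]) - share)) {
      growing[ord[k + 1]] <- TRUE
    }
    # one refinement pass: toggle taxa that bring the realized share closer
    cur <- sum(w[growing])
    for (i in sample.int(n)) {
      cand <- if (growing[i]) cur - w[i] else cur + w[i]
      if (abs(cand - share) < abs(cur - share)) {
        growing[i] <- !growing[i]
        cur <- cand
      }
    }
  }
  hi <- min(afe_water, eaf_max(constants))
  if (hi <= 0.05) abort("soil-water enrichment too low to support growing taxa (EAF > 0.05)")
  eaf <- numeric(n)
  eaf[growing] <- 0.05 + (hi - 0.05) * rbeta(sum(growing), 2, 4)
  dplyr::mutate(base, true_eaf = eaf, growing = growing)
}

#' Simulate a soil community with known growth structure
#'
#' Draws a community of taxa with lognormal abundances, uniform GC contents
#' in 0.3-0.7, unlabeled buoyant densities from the linear density-GC
#' relation (with taxon-level scatter), and a ground-truth \eqn{^{18}}O
#' excess atom fraction per taxon. The scenario sets which share of community
#' 16S copies belongs to growing taxa (APE > 5%).
#'
#' @param n_taxa number of taxa (>= 10).
#' @param scenario preset name or numeric growing share; see [qsip_design()].
#' @param seed integer seed.
#' @param afe_water soil-water \eqn{^{18}}O atom fraction excess (decimal)
#'   bounding the attainable EAF.
#' @param wlight_sd taxon-level scatter (g/mL) around the density-GC line.
#' @param constants [qsip_constants()].
#' @return A tibble with one row per taxon: `taxon_id`, seven taxonomy ranks,
#'   `gc`, `w_light`, `base_abundance`, `true_eaf`, `growing`.
#' @examples
#' com <- simulate_community(100, "ambient", seed = 1)
#' sum(com$base_abundance[com$growing]) / sum(com$base_abundance)
#' @export
simulate_community <- function(n_taxa, scenario, seed, afe_water = 0.593,
                               wlight_sd = 0.002,
                               constants = qsip_constants()) {
  share <- scenario_growing_share(scenario)
  base <- simulate_taxa_base(n_taxa, seed, wlight_sd, constants)
  assign_growth(base, share, afe_water, derive_seed(seed, "growth"), constants)
}

#' Labeled buoyant density implied by a true excess atom fraction
#'
#' Exact inverse of [excess_atom_fraction()]: from a taxon's GC content,
#' unlabeled density and true EAF, compute the buoyant density its labeled
#' DNA equilibrates at. Used by the simulator to place labeled DNA, and as
#' the round-trip oracle for the estimator.
#'
#' @param gc GC content (fraction in 0-1).
#' @param w_light unlabeled buoyant density (g/mL).
#' @param eaf excess atom fraction \eqn{^{18}}O in `[0, 1 - nat_abund]`.
#' @param constants [qsip_constants()].
#' @return Labeled buoyant density (g/mL). Vectorized.
#' @examples
#' wad_shift_from_eaf(0.5, 1.687810, 0.5)
#' @export
wad_shift_from_eaf <- function(gc, w_light, eaf, constants = qsip_constants()) {
  if (any(eaf < 0 | eaf > eaf_max(constants))) {
    abort(sprintf("`eaf` must lie in [0, %.9f]", eaf_max(constants)))
  }
  m_light <- constants$mw_gc_slope * gc + constants$mw_gc_intercept
  m_lab <- m_light + (eaf / (1 - constants$nat_abund_18O)) *
    constants$mw_18O_max_shift
  w_light * m_lab / m_light
}

# Gaussian partial moments over [a, b]: total mass and first moment.
gauss_partial <- function(a, b, mu, sigma) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  mass <- pnorm(be) - pnorm(al)
  m1 <- mu * mass - sigma * (dnorm(be) - dnorm(al))
  list(mass = mass, m1 = m1)
}

# Allocate each taxon's Gaussian DNA mass onto the fraction density points
# with triangular (cloud-in-cell) weights: mass at position x is split
# linearly between the two nearest grid points, which preserves the first
# moment exactly, so the density-weighted mean over fractions recovers the
# taxon's center up to tail truncation at the grid edges.
# Returns an n_taxa x n_fractions weight matrix (rows sum to ~1).
cic_weights <- function(mu, sigma, centers) {
  h <- abs(centers[2] - centers[1])
  n_t <- length(mu)
  n_f <- length(centers)
  W <- matrix(0, n_t, n_f)
  for (f in seq_len(n_f)) {
    d <- centers[f]
    lo <- gauss_partial(d - h, d, mu, sigma)
    hi <- gauss_partial(d, d + h, mu, sigma)
    W[, f] <- (lo$m1 - (d - h) * lo$mass) / h + ((d + h) * hi$mass - hi$m1) / h
  }
  # far tails can round to ~ -1e-17; weights are masses and must be >= 0
  pmax(W, 0)
}

#' Simulate the gradient fractions of one tube
#'
#' Each taxon's DNA mass spreads over the density grid as a Gaussian centered
#' on its tube-level weighted average density — `w_light` for
#' natural-abundance tubes, [wad_shift_from_eaf()] of its true EAF for
#' labeled tubes — with spread `sigma_d`. Reads are drawn multinomially over
#' taxon-by-fraction cells from copy proportions; ddPCR totals get lognormal
#' measurement noise; density readings get Gaussian jitter.
#'
#' @param profiles community tibble from [simulate_community()].
#' @param isotope `"18O"` (labeled) or `"16O"` (natural abundance).
#' @param design a [qsip_design()].
#' @param tube_id id string recorded in the outputs.
#' @param seed tube-level seed.
#' @return A list with tibbles `fractions` (`tube_id`, `fraction_index`,
#'   `density`, `total_copies`, `total_read_pairs`) and `counts` (`tube_id`,
#'   `fraction_index`, `taxon_id`, `reads`).
#' @examples
#' des <- qsip_design(n_taxa = 20, replicates = 2, reads_per_tube = 2000, seed = 1)
#' com <- simulate_community(20, "ambient", seed = 1)
#' tube <- simulate_tube(com, "18O", des, tube_id = "demo", seed = 42)
#' head(tube$fractions)
#' @export
simulate_tube <- function(profiles, isotope = c("18O", "16O"), design,
                          tube_id = "tube1", seed = 1L) {
  isotope <- match.arg(isotope)
  if (nrow(profiles) == 0) abort("`profiles` must contain at least one taxon")
  noise <- design$noise
  set.seed(seed)

  n_f <- design$n_fractions
  h <- diff(design$density_range) / n_f
  if (h > 2 * design$sigma_d) {
    warn(sprintf(
      "density grid is coarse for sigma_d = %g g/mL (bin width %g > 2*sigma_d): WADs will be poorly resolved",
      design$sigma_d, h
    ))
  }
  # fraction 1 is the heaviest (tubes are collected bottom-up)
  centers <- design$density_range[2] - h / 2 - (seq_len(n_f) - 1) * h

  mu <- if (isotope == "18O") {
    wad_shift_from_eaf(profiles$gc, profiles$w_light, profiles$true_eaf)
  } else {
    profiles$w_light
  }
  abund <- profiles$base_abundance *
    rlnorm(nrow(profiles), 0, noise$tube_abund_sdlog)
  W <- cic_weights(mu, design$sigma_d, centers)
  copies <- abund * W # n_taxa x n_fractions

  # per-fraction library depth: fixed-cycle PCR saturates the yield of any
  # fraction holding appreciable template, so depth follows a Michaelis-type
  # curve in the fraction's DNA share rather than the share itself; the
  # composition WITHIN a fraction stays proportional to template copies
  frac_copies0 <- colSums(copies)
  k_sat <- design$pcr_saturation * sum(frac_copies0)
  depth_w <- frac_copies0 / (frac_copies0 + k_sat)
  cell_p <- sweep(copies, 2,
                  ifelse(frac_copies0 > 0, depth_w / frac_copies0, 0), `*`)

  if (noise$reads == "multinomial") {
    reads <- copies
    reads[] <- rmultinom(1, design$reads_per_tube, prob = as.vector(cell_p))
  } else {
    reads <- design$reads_per_tube * cell_p / sum(cell_p)
  }

  frac_copies <- colSums(copies)
  fractions <- tibble::tibble(
    tube_id = tube_id,
    fraction_index = seq_len(n_f),
    density = centers + rnorm(n_f, 0, noise$density_sd),
    total_copies = frac_copies * rlnorm(n_f, 0, noise$ddpcr_sdlog),
    total_read_pairs = colSums(reads)
  )
  counts <- tibble::tibble(
    tube_id = tube_id,
    fraction_index = rep(seq_len(n_f), each = nrow(profiles)),
    taxon_id = rep(profiles$taxon_id, n_f),
    reads = as.vector(reads)
  )
  counts <- counts[counts$reads > 0, , drop = FALSE]
  list(fractions = fractions, counts = counts)
}

#' Simulate a complete vapor-qSIP experiment with ground truth
#'
#' Builds one base community, assigns a treatment-specific growing structure
#' per scenario, simulates every tube of the full design (labeled and
#' natural-abundance per replicate), and returns the pipeline's four input
#' tables alongside the generating truth.
#'
#' @param design a [qsip_design()].
#' @return An object of class `qsip_simulation`: list with
#'   \describe{
#'     \item{data}{a [qsip_data()] bundle (`counts`, `fractions`, `samples`,
#'       `taxonomy`) ready for the estimation pipeline.}
#'     \item{truth}{list with `taxa` (per taxon x treatment: `true_eaf`,
#'       `true_rgr`, `growing`), `growing_share` (per treatment, percent of
#'       community copies in growing taxa), `abundances` (true per-tube taxon
#'       copies), and the base `profiles`.}
#'     \item{design}{the design used.}
#'   }
#' @examples
#' sim <- simulate_experiment(qsip_design(
#'   scenarios = c("ambient", "drought"), n_taxa = 40, replicates = 2,
#'   reads_per_tube = 5000, seed = 7
#' ))
#' names(sim$data)
#' sim$truth$growing_share
#' @export
simulate_experiment <- function(design) {
  if (!inherits(design, "qsip_design")) abort("`design` must be a `qsip_design`")
  constants <- qsip_constants()
  set.seed(design$seed)
  ape_water <- design$soil_water_ape %||% runif(nrow(design$treatments), 55, 64)

  base <- simulate_taxa_base(design$n_taxa, derive_seed(design$seed, "community"),
                             design$noise$wlight_sd, constants)

  per_trt <- purrr::map(seq_len(nrow(design$treatments)), function(i) {
    trt <- design$treatments$treatment[i]
    afe <- ape_water[i] / 100
    prof <- assign_growth(base, scenario_growing_share(design$treatments$scenario[[i]]),
                          afe, derive_seed(design$seed, paste0("growth_", trt)),
                          constants)
    prof
  })
  names(per_trt) <- design$treatments$treatment

  tubes <- tidyr::expand_grid(
    treatment = design$treatments$treatment,
    replicate = seq_len(design$replicates),
    isotope = c("18O", "16O")
  ) |>
    dplyr::mutate(tube_id = paste(.data$treatment, paste0("r", .data$replicate),
                                  .data$isotope, sep = "_"))

  sims <- purrr::pmap(tubes, function(treatment, replicate, isotope, tube_id) {
    simulate_tube(per_trt[[treatment]], isotope, design, tube_id,
                  seed = derive_seed(design$seed, tube_id))
  })
  fractions <- dplyr::bind_rows(purrr::map(sims, "fractions"))
  counts <- dplyr::bind_rows(purrr::map(sims, "counts"))

  if (!is.null(design$drop_lightest)) {
    for (tid in names(design$drop_lightest)) {
      n_drop <- design$drop_lightest[[tid]]
      tf <- fractions[fractions$tube_id == tid, ]
      # lose the lightest fractions that actually hold DNA (>= 0.5% of the
      # tube's copies); losing DNA-free tail fractions would be invisible
      tf <- tf[tf$total_copies >= 0.005 * sum(tf$total_copies), ]
      drop_idx <- tf$fraction_index[order(tf$density)][seq_len(n_drop)]
      keep <- !(fractions$tube_id == tid & fractions$fraction_index %in% drop_idx)
      fractions <- fractions[keep, ]
      keep_c <- !(counts$tube_id == tid & counts$fraction_index %in% drop_idx)
      counts <- counts[keep_c, ]
    }
  }

  samples <- tubes |>
    dplyr::left_join(design$treatments, by = "treatment") |>
    dplyr::left_join(
      tibble::tibble(treatment = design$treatments$treatment,
                     soil_water_ape = ape_water),
      by = "treatment"
    ) |>
    dplyr::mutate(
      incubation_days = design$incubation_days,
      soil_water_ape = ifelse(.data$isotope == "18O", .data$soil_water_ape, NA_real_)
    ) |>
    dplyr::select("tube_id", "treatment", "replicate", "isotope", "drought",
                  "climate", "incubation_days", "soil_water_ape")

  taxonomy <- dplyr::select(base, "taxon_id", "domain", "phylum", "class",
                            "order", "family", "genus", "species")

  truth_taxa <- purrr::imap_dfr(per_trt, function(prof, trt) {
    afe <- ape_water[match(trt, design$treatments$treatment)] / 100
    tibble::tibble(
      treatment = trt, taxon_id = prof$taxon_id, gc = prof$gc,
      w_light = prof$w_light, true_eaf = prof$true_eaf,
      true_rgr = prof$true_eaf / (afe * design$incubation_days),
      growing = prof$growing
    )
  })
  truth_share <- purrr::imap_dfr(per_trt, function(prof, trt) {
    tibble::tibble(
      treatment = trt,
      growing_share_pct = 100 * sum(prof$base_abundance[prof$growing]) /
        sum(prof$base_abundance)
    )
  })
  truth_abund <- tibble::tibble(
    tube_id = rep(tubes$tube_id, each = design$n_taxa),
    taxon_id = rep(base$taxon_id, nrow(tubes)),
    true_copies = rep(base$base_abundance, nrow(tubes))
  )

  structure(
    list(
      data = qsip_data(counts = counts, fractions = fractions,
                       samples = samples, taxonomy = taxonomy),
      truth = list(taxa = truth_taxa, growing_share = truth_share,
                   abundances = truth_abund, profiles = base,
                   soil_water_ape = setNames(ape_water, design$treatments$treatment)),
      design = design
    ),
    class = "qsip_simulation"
  )
}

#' @export
print.qsip_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic vapor-qSIP experiment: %d taxa, %d treatments x %d replicates x 2 isotopes (%d tubes), %d fractions/tube\n",
    x$design$n_taxa, nrow(x$design$treatments), x$design$replicates,
    nrow(x$design$treatments) * x$design$replicates * 2, x$design$n_fractions
  ))
  print(x$truth$growing_share)
  invisible(x)
}
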