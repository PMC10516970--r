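# Fixtures built in code and shared across test files.

# small default-noise experiment, simulated once per session
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(qsip_design(
        scenarios = c("ambient", "drought"), n_taxa = 60, replicates = 3,
        reads_per_tube = 30000, seed = 401
      ))
    }
    cache
  }
})

# hand-built single-tube dataset with explicit densities/reads/copies.
# fractions: list of (density, total_copies, total_read_pairs)
# reads: taxa x fractions matrix
toy_tube_data <- function(densities, total_copies, total_read_pairs, reads,
                          taxon_ids = paste0("t", seq_len(nrow(reads))),
                          tube_id = "tube1", isotope = "18O",
                          treatment = "ambient", replicate = 1) {
  n_f <- length(densities)
  counts <- tibble::tibble(
    tube_id = tube_id,
    fraction_index = rep(seq_len(n_f), each = nrow(reads)),
    taxon_id = rep(taxon_ids, n_f),
    reads = as.vector(reads)
  )
  counts <- counts[counts$reads > 0, ]
  fractions <- tibble::tibble(
    tube_id = tube_id, fraction_index = seq_len(n_f), density = densities,
    total_copies = total_copies, total_read_pairs = total_read_pairs
  )
  samples <- tibble::tibble(
    tube_id = tube_id, treatment = treatment, replicate = replicate,
    isotope = isotope, drought = "no", climate = "ambient",
    incubation_days = 5, soil_water_ape = ifelse(isotope == "18O", 59.3, NA)
  )
  taxonomy <- tibble::tibble(
    taxon_id = taxon_ids, domain = "Bacteria", phylum = "Proteobacteria",
    class = NA_character_, order = NA_character_, family = NA_character_,
    genus = NA_character_, species = NA_character_
  )
  qsip_data(counts, fractions, samples, taxonomy)
}

# four treatment growing sets realizing prescribed Venn region counts;
# every region gets synthetic taxon ids
sets_from_regions <- function(regions) {
  ids <- character(0)
  sets <- list()
  counter <- 0
  for (membership in names(regions)) {
    n <- regions[[membership]]
    if (n == 0) next
    members <- strsplit(membership, "&", fixed = TRUE)[[1]]
    new_ids <- sprintf("taxon_%s_%d", gsub("&", "", membership),
                       seq_len(n) + counter)
    counter <- counter + n
    for (s in members) sets[[s]] <- c(sets[[s]], new_ids)
  }
  sets
}
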