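default_components <- function() {
  tibble(
    component = c(
      "permanent_epidermis", "fibroblast", "anagen_hf", "vascular",
      "immune", "miscellaneous", "schwann", "melanocyte"
    ),
    population = c(
      "permanent_epidermis", "fibroblast", "anagen_hf", "vascular",
      "immune", "miscellaneous", "neural_crest", "neural_crest"
    ),
    subpopulation = c("", "", "", "", "", "", "schwann", "melanocyte")
  )
}

# Stated world: plucked anagen follicles are almost entirely follicle
# keratinocytes plus bulb melanocytes; biopsies spread across the
# interfollicular populations, each represented strongly enough that a
# fold-8 marker leaves a detectable bulk fold change at desk scale.
# Columns sum to 1; rows follow default_components().
default_compositions <- function() {
  m <- cbind(
    #            epid  fibro anagen vasc  immune misc  schwann melano
    plucked = c(0.015, 0.020, 0.710, 0.008, 0.008, 0.005, 0.004, 0.230),
    biopsy  = c(0.140, 0.185, 0.060, 0.130, 0.130, 0.125, 0.215, 0.015)
  )
  rownames(m) <- default_components()$component
  m
}

default_sample_sheet <- function() {
  grid <- tibble(
    site = c(rep("forelock", 4), rep("mane", 3)),
    subject_id = c("h1", "h2", "h3", "h4", "h1", "h2", "h3")
  )
  dplyr::bind_rows(
    mutate(grid, source = "plucked"),
    mutate(grid, source = "biopsy")
  ) |>
    mutate(sample_id = sprintf("%s_%s_%s", .data$source, .data$site, .data$subject_id)) |>
    select("sample_id", "source", "site", "subject_id")
}

#' Configure the mixture-count simulation
#'
#' The generator emulates the world the analysis assumes: every bulk sample is
#' a negative-binomial draw around a mixture of cell-population expression
#' profiles whose mixing proportions depend on the sampling source. Plucked
#' hair up-weights the anagen hair-follicle keratinocytes and the melanocyte
#' subpopulation of the neural-crest-derived cells; skin biopsies up-weight
#' the interfollicular populations (permanent epidermis keratinocytes,
#' fibroblasts, vascular, immune, miscellaneous cells) and the Schwann
#' subpopulation. Marker genes are elevated `marker_fold`-fold in their own
#' population's profile only.
#'
#' @param n_genes Number of genes (default 5000).
#' @param markers_per_population True marker genes per main population
#'   (default 10; the neural-crest allocation is split evenly between its
#'   Schwann and melanocyte subpopulations).
#' @param marker_fold Expression fold elevation of a marker in its own
#'   population (default 8).
#' @param base_meanlog,base_sdlog Log-normal parameters of the shared baseline
#'   expression rates (defaults 4 and 1.2).
#' @param dispersion NB dispersion of the count draws (default 0.1; 0 gives
#'   Poisson counts).
#' @param library_size_range Uniform range of per-sample library sizes
#'   (default 3e5 to 6e5; a desk-scaled sequencing depth).
#' @param samples Sample sheet to simulate; defaults to the study design of
#'   seven plucked plus seven biopsy samples (four forelock, three mane per
#'   source, shared subjects).
#' @param compositions Numeric matrix, mixture components by sources
#'   (`plucked`, `biopsy` columns); each column must sum to 1.
#' @param components Component table (`component`, `population`,
#'   `subpopulation`) matching the rows of `compositions`.
#' @param fraction_multi_population_markers Fraction of genes emitted in the
#'   reference as significant under two populations, to exercise the
#'   unique-marker exclusion rule (default 0.05).
#' @param fraction_unmapped_orthologs Fraction of genes omitted from the
#'   ortholog map (default 0.05).
#' @param ref_detected_fraction Fraction of genes detected ("expressed") in
#'   the reference dataset (default 0.85).
#' @param seed Base random seed (default 1).
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_genes = 5000,
                              markers_per_population = 10,
                              marker_fold = 8,
                              base_meanlog = 4,
                              base_sdlog = 1.2,
                              dispersion = 0.1,
                              library_size_range = c(3e5, 6e5),
                              samples = default_sample_sheet(),
                              compositions = default_compositions(),
                              components = default_components(),
                              fraction_multi_population_markers = 0.05,
                              fraction_unmapped_orthologs = 0.05,
                              ref_detected_fraction = 0.85,
                              seed = 1) {
  if (marker_fold <= 0) abort("`marker_fold` must be positive.")
  if (dispersion < 0) abort("`dispersion` must be non-negative.")
  if (!setequal(rownames(compositions), components$component) ||
      !identical(sort(colnames(compositions)), sort(c("plucked", "biopsy")))) {
    abort("`compositions` must have one row per component and columns plucked/biopsy.")
  }
  compositions <- compositions[components$component, c("plucked", "biopsy"), drop = FALSE]
  if (any(compositions < 0)) abort("Composition proportions must be non-negative.")
  sums <- colSums(compositions)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("Each composition column must sum to 1 (within 1e-9).")
  }
  samples <- validate_sample_sheet(samples)
  n_pop <- dplyr::n_distinct(components$population)
  if (markers_per_population * n_pop > n_genes) {
    abort("markers_per_population x n_populations exceeds n_genes.")
  }
  structure(
    list(
      n_genes = n_genes,
      markers_per_population = markers_per_population,
      marker_fold = marker_fold,
      base_meanlog = base_meanlog,
      base_sdlog = base_sdlog,
      dispersion = dispersion,
      library_size_range = library_size_range,
      samples = samples,
      compositions = compositions,
      components = components,
      fraction_multi_population_markers = fraction_multi_population_markers,
      fraction_unmapped_orthologs = fraction_unmapped_orthologs,
      ref_detected_fraction = ref_detected_fraction,
      seed = seed
    ),
    class = "sim_config"
  )
}

# expected marker votes per population, and the resulting expected calls,
# derived from the composition differences of each marker's own component
expected_truth <- function(markers, components, compositions,
                           conclusive_threshold = 0.75) {
  comp_dir <- sign(compositions[, "plucked"] - compositions[, "biopsy"])
  markers$expected_direction <- ifelse(
    comp_dir[markers$component] > 0, "plucked_higher",
    ifelse(comp_dir[markers$component] < 0, "biopsy_higher", "none")
  )
  pop_calls <- markers |>
    group_by(.data$population) |>
    summarise(
      n_markers = dplyr::n(),
      n_biopsy = sum(.data$expected_direction == "biopsy_higher"),
      n_plucked = sum(.data$expected_direction == "plucked_higher"),
      .groups = "drop"
    ) |>
    mutate(expected_call = purrr::map2_chr(
      .data$n_biopsy, .data$n_plucked,
      ~ direction_call(.x, .y, conclusive_threshold)
    ))
  sub_calls <- markers |>
    filter(.data$subpopulation != "") |>
    group_by(.data$population, .data$subpopulation) |>
    summarise(
      n_markers = dplyr::n(),
      n_biopsy = sum(.data$expected_direction == "biopsy_higher"),
      n_plucked = sum(.data$expected_direction == "plucked_higher"),
      .groups = "drop"
    ) |>
    mutate(expected_call = dplyr::case_when(
      .data$n_biopsy > .data$n_plucked ~ "biopsy_enriched",
      .data$n_plucked > .data$n_biopsy ~ "plucked_enriched",
      .default = "inconclusive"
    ))
  list(
    markers = markers,
    population_calls = pop_calls,
    subpopulation_calls = sub_calls,
    compositions = compositions
  )
}

#' Generate population expression profiles
#'
#' Baseline expression rates are drawn log-normal per gene and shared across
#' mixture components; each marker gene's rate is multiplied by
#' `marker_fold` in its own component only. Deterministic given
#' `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param seed Random seed (defaults to `config$seed`).
#' @return A `sim_profiles` list: `profiles` (genes-by-components rate
#'   matrix) and `truth` (marker labels with expected directions,
#'   per-population expected calls, and the composition matrix).
#' @export
generate_profiles <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  lambda <- rlnorm(n, config$base_meanlog, config$base_sdlog)
  comp <- config$components
  # allocate markers: whole quota per population, split evenly across its
  # subpopulation components when it has any
  alloc <- comp |>
    group_by(.data$population) |>
    mutate(n_markers = {
      k <- dplyr::n()
      base <- config$markers_per_population %/% k
      extra <- config$markers_per_population %% k
      base + as.integer(dplyr::row_number() <= extra)
    }) |>
    ungroup()
  total <- sum(alloc$n_markers)
  marker_genes <- sample(genes, total)
  markers <- tibble(
    gene_id = marker_genes,
    component = rep(alloc$component, alloc$n_markers),
    population = rep(alloc$population, alloc$n_markers),
    subpopulation = rep(alloc$subpopulation, alloc$n_markers)
  )
  profiles <- matrix(
    lambda, nrow = n, ncol = nrow(comp),
    dimnames = list(genes, comp$component)
  )
  idx <- cbind(match(markers$gene_id, genes), match(markers$component, comp$component))
  profiles[idx] <- profiles[idx] * config$marker_fold
  structure(
    list(
      profiles = profiles,
      truth = expected_truth(markers, comp, config$compositions)
    ),
    class = "sim_profiles"
  )
}

#' Generate bulk counts from mixed population profiles
#'
#' For a sample with source s and library size \eqn{N_j}, the expected count
#' of gene g is \eqn{N_j \sum_p c_s[p]\,\pi_{gp} / Z_s} where \eqn{\pi} are
#' the component profiles, \eqn{c_s} the source's composition vector, and
#' \eqn{Z_s} the normalizing sum over genes — so library size is independent
#' of composition. Counts are drawn NB with the configured dispersion
#' (Poisson when 0).
#'
#' @param profiles A `sim_profiles` from [generate_profiles()].
#' @param config The same [simulation_config()].
#' @param seed Random seed (defaults to `config$seed + 1`).
#' @return List with `counts` (a [count_matrix()]), `sheet` (sample sheet
#'   tibble), and `truth` (carried through).
#' @export
generate_bulk_counts <- function(profiles, config, seed = config$seed + 1) {
  set.seed(seed)
  sheet <- config$samples
  pr <- profiles$profiles
  mix <- pr %*% config$compositions        # genes x sources
  mix <- sweep(mix, 2, colSums(mix), "/")  # per-source gene proportions
  libs <- runif(nrow(sheet), config$library_size_range[1], config$library_size_range[2])
  counts <- vapply(seq_len(nrow(sheet)), function(j) {
    mu <- libs[j] * mix[, sheet$source[j]]
    if (config$dispersion == 0) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
    }
  }, numeric(nrow(pr)))
  dimnames(counts) <- list(rownames(pr), sheet$sample_id)
  list(
    counts = count_matrix(counts),
    sheet = sheet,
    truth = profiles$truth
  )
}

#' Generate the matching reference tables
#'
#' Emits the true markers as significant under their own population (with
#' their subpopulation annotation), plus a configured fraction of extra
#' background genes as significant under two populations each — exercising
#' the unique-marker exclusion rule — and an identity ortholog map with a
#' configured unmapped fraction. Also returns the reference-side expressed
#' and significant gene sets.
#'
#' @param truth The `truth` element produced by the generators.
#' @param config The same [simulation_config()].
#' @param seed Random seed (defaults to `config$seed + 2`).
#' @return List with `reference` (validated marker reference), `orthologs`
#'   (map tibble), `ref_expressed`, `ref_significant`.
#' @export
generate_reference_tables <- function(truth, config, seed = config$seed + 2) {
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  markers <- truth$markers
  marker_rows <- tibble(
    gene_id = markers$gene_id,
    population = markers$population,
    subpopulation = markers$subpopulation,
    significant = TRUE
  )
  n_multi <- round(config$fraction_multi_population_markers * config$n_genes)
  non_marker <- setdiff(genes, markers$gene_id)
  multi_genes <- sample(non_marker, min(n_multi, length(non_marker)))
  pops <- unique(config$components$population)
  multi_rows <- dplyr::bind_rows(lapply(multi_genes, function(g) {
    tibble(
      gene_id = g,
      population = sample(pops, 2),
      subpopulation = "",
      significant = TRUE
    )
  }))
  reference <- validate_marker_reference(
    dplyr::bind_rows(marker_rows, multi_rows),
    populations = unique(config$components$population)
  )
  ref_significant <- unique(reference$gene_id)
  n_expressed <- round(config$ref_detected_fraction * config$n_genes)
  background <- setdiff(genes, ref_significant)
  extra_expressed <- sample(background, max(0, min(n_expressed - length(ref_significant),
                                                   length(background))))
  ref_expressed <- union(ref_significant, extra_expressed)
  n_unmapped <- round(config$fraction_unmapped_orthologs * config$n_genes)
  unmapped <- if (n_unmapped > 0) sample(genes, min(n_unmapped, length(genes))) else character(0)
  mapped <- setdiff(genes, unmapped)
  list(
    reference = reference,
    orthologs = tibble(study_gene_id = mapped, reference_gene_id = mapped),
    ref_expressed = ref_expressed,
    ref_significant = ref_significant
  )
}

#' Simulate a complete experiment
#'
#' One call producing everything the pipeline consumes: counts, sample sheet,
#' marker reference, ortholog map, reference expressed/significant sets, and
#' the ground truth for parameter-recovery checks.
#'
#' @param config A [simulation_config()].
#' @param seed Base seed (defaults to `config$seed`); the three generator
#'   stages use `seed`, `seed + 1`, `seed + 2`.
#' @return List with elements `counts`, `sheet`, `reference`, `orthologs`,
#'   `ref_expressed`, `ref_significant`, `truth`, `config`.
#' @export
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 200, seed = 7))
#' sim$counts
simulate_experiment <- function(config = simulation_config(), seed = config$seed) {
  profiles <- generate_profiles(config, seed = seed)
  bulk <- generate_bulk_counts(profiles, config, seed = seed + 1)
  tables <- generate_reference_tables(profiles$truth, config, seed = seed + 2)
  list(
    counts = bulk$counts,
    sheet = bulk$sheet,
    reference = tables$reference,
    orthologs = tables$orthologs,
    ref_expressed = tables$ref_expressed,
    ref_significant = tables$ref_significant,
    truth = profiles$truth,
    config = config
  )
}
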