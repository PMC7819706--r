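#' Typical proteome amino-acid frequencies
#'
#' Baseline composition for the synthetic generator, close to average
#' eukaryotic proteome frequencies; renormalized to sum to 1.
#'
#' @return Named 20-vector of fractions.
#' @export
baseline_aa_frequencies <- function() {
  f <- c(A = 0.083, C = 0.014, D = 0.054, E = 0.067, F = 0.039, G = 0.071,
         H = 0.023, I = 0.059, K = 0.058, L = 0.096, M = 0.024, N = 0.041,
         P = 0.047, Q = 0.039, R = 0.055, S = 0.066, T = 0.053, V = 0.069,
         W = 0.011, Y = 0.029)
  f / sum(f)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a clade-labelled
#' species tree (animals, plants, fungi plus an Excavata outgroup), pfam
#' birth/loss histories spanning strata from LUCA to recent, per-instance
#' sequences whose composition, hydrophobic clustering and disorder drift
#' with true age at configurable lineage-specific rates, and injected
#' random-presence contaminants.
#'
#' Planted trends: the hydrophobic fraction of a pfam's target composition
#' is `baseline + hydrophobic_slope[lineage] * age_BY`; the target
#' clustering index is `clustering_intercept + clustering_slope * age_BY`
#' (universal across lineages); mean disorder follows hydrophilic content
#' through the propensity table, giving a planted disorder slope of
#' `-(disorder_hi - disorder_lo) * hydrophobic_slope[lineage] +
#' disorder_slope[lineage]` per BY.
#'
#' @param seed Integer seed; every artifact is reproducible from it.
#' @param n_animal,n_plant,n_fungi,n_excavata Leaves per clade (>= 2).
#' @param strata A [stratum_config()].
#' @param crown_animal,crown_plant,crown_fungi,crown_excavata,opisthokont_split
#'   Within-tree calibration ages (MY).
#' @param pfam_counts Named counts per stratum: `luca`, `post_luca`, `feca`,
#'   `basal`, `recent_animal`, `recent_plant`, `recent_fungi`.
#' @param loss_rate Loss events per branch per 100 MY.
#' @param n_contaminants Injected random-presence pfams.
#' @param contaminant_k Range `c(min, max)` of contaminant carrier counts.
#' @param baseline_composition Named 20-vector summing to 1.
#' @param hydrophobic_slope Named fractions-per-BY for `animal`, `plant`,
#'   `fungi`, `ancient`.
#' @param ancient_hydrophobic_offset Constant added to the target
#'   hydrophobic fraction of ancient-strata pfams, keeping the planted
#'   composition continuous where the recent animal trend meets the flat
#'   ancient regime (ancient domains end up more hydrophobic, hence less
#'   disordered, than young ones — the level structure seen in real
#'   phylostratigraphies). Defaults to the animal slope times the age of
#'   the animal/plant split.
#' @param disorder_slope Additional direct disorder change per BY, same names.
#' @param clustering_intercept,clustering_slope Target psi at age 0 and its
#'   universal change per BY.
#' @param pfam_jitter_h,pfam_jitter_psi,pfam_jitter_comp Per-pfam biological
#'   variation (sd of hydrophobic fraction, of target psi, lognormal sd of
#'   within-group composition).
#' @param length_range Integer range of instance lengths (residues).
#' @param disorder_lo,disorder_hi,disorder_window Propensity of hydrophobic /
#'   hydrophilic residues and smoothing window for surrogate disorder.
#' @param multi_domain_frac Fraction of first-eukaryote pfams paired into
#'   two-domain genes (exercises co-occurrence grouping).
#' @param tm_frac Fraction of pfams given transmembrane helices.
#' @param n_filter_decoys Named counts of metadata decoys exercising the
#'   quality filters: `prokaryote_only`, `unannotated`, `no_abstract`,
#'   `organelle`, `viral`, `rescued`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_animal = 24L, n_plant = 16L, n_fungi = 12L,
                       n_excavata = 8L,
                       strata = stratum_config(),
                       crown_animal = 700, crown_plant = 900,
                       crown_fungi = 800, crown_excavata = 1800,
                       opisthokont_split = 1105,
                       pfam_counts = c(luca = 60L, post_luca = 90L,
                                       feca = 70L, basal = 120L,
                                       recent_animal = 260L,
                                       recent_plant = 120L,
                                       recent_fungi = 80L),
                       loss_rate = 0.01,
                       n_contaminants = 40L,
                       contaminant_k = c(3L, 10L),
                       baseline_composition = baseline_aa_frequencies(),
                       hydrophobic_slope = c(animal = 0.03, plant = 0,
                                             fungi = 0, ancient = 0),
                       ancient_hydrophobic_offset = 0.045,
                       disorder_slope = c(animal = 0, plant = 0,
                                          fungi = 0, ancient = 0),
                       clustering_intercept = 1.35,
                       clustering_slope = -0.07,
                       pfam_jitter_h = 0.02,
                       pfam_jitter_psi = 0.04,
                       pfam_jitter_comp = 0.08,
                       length_range = c(90L, 210L),
                       disorder_lo = 0.05, disorder_hi = 0.90,
                       disorder_window = 11L,
                       multi_domain_frac = 0.1,
                       tm_frac = 0.10,
                       n_filter_decoys = c(prokaryote_only = 4L,
                                           unannotated = 4L,
                                           no_abstract = 4L, organelle = 4L,
                                           viral = 4L, rescued = 4L)) {
  stopifnot(n_animal >= 2L, n_plant >= 2L, n_fungi >= 2L, n_excavata >= 2L,
            loss_rate >= 0, n_contaminants >= 0L,
            crown_animal < opisthokont_split,
            crown_fungi < opisthokont_split,
            opisthokont_split < strata$animal_plant_split,
            crown_plant < strata$animal_plant_split,
            crown_excavata < strata$feca_excavata_age,
            length_range[1] >= 12L, length_range[1] <= length_range[2],
            pfam_jitter_h >= 0, pfam_jitter_psi >= 0, pfam_jitter_comp >= 0,
            disorder_lo >= 0, disorder_hi <= 1, disorder_lo < disorder_hi)
  baseline_composition <- baseline_composition[AA_STANDARD]
  stopifnot(!anyNA(baseline_composition))
  baseline_composition <- baseline_composition / sum(baseline_composition)
  structure(list(
    seed = as.integer(seed), n_animal = n_animal, n_plant = n_plant,
    n_fungi = n_fungi, n_excavata = n_excavata, strata = strata,
    crown_animal = crown_animal, crown_plant = crown_plant,
    crown_fungi = crown_fungi, crown_excavata = crown_excavata,
    opisthokont_split = opisthokont_split, pfam_counts = pfam_counts,
    loss_rate = loss_rate, n_contaminants = n_contaminants,
    contaminant_k = contaminant_k,
    baseline_composition = baseline_composition,
    hydrophobic_slope = hydrophobic_slope,
    ancient_hydrophobic_offset = ancient_hydrophobic_offset,
    disorder_slope = disorder_slope,
    clustering_intercept = clustering_intercept,
    clustering_slope = clustering_slope,
    pfam_jitter_h = pfam_jitter_h, pfam_jitter_psi = pfam_jitter_psi,
    pfam_jitter_comp = pfam_jitter_comp,
    length_range = as.integer(length_range),
    disorder_lo = disorder_lo, disorder_hi = disorder_hi,
    disorder_window = as.integer(disorder_window),
    multi_domain_frac = multi_domain_frac, tm_frac = tm_frac,
    n_filter_decoys = n_filter_decoys
  ), class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key-value document mirroring the [sim_config()] arguments; absent
#' keys take the defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  for (nm in c("pfam_counts", "hydrophobic_slope", "disorder_slope",
               "n_filter_decoys", "baseline_composition")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  if (!is.null(vals$strata)) vals$strata <- do.call(stratum_config, as.list(vals$strata))
  do.call(sim_config, vals)
}

# random coalescent-style ultrametric subtree as a newick fragment
coalescent_newick <- function(labels, crown_age) {
  n <- length(labels)
  if (n == 1L) return(list(newick = labels, height = 0))
  nodes <- as.list(labels)
  heights <- rep(0, n)
  times <- c(sort(runif(n - 2L, 0, crown_age)), crown_age)
  for (t in times) {
    i <- sort(sample.int(length(nodes), 2L))
    nw <- sprintf("(%s:%.6f,%s:%.6f)", nodes[[i[1]]], t - heights[i[1]],
                  nodes[[i[2]]], t - heights[i[2]])
    nodes <- c(nodes[-i], list(nw))
    heights <- c(heights[-i], t)
  }
  list(newick = nodes[[1]], height = crown_age)
}

#' Simulate the clade-labelled ultrametric species tree
#'
#' Plants diverge from animals+fungi at the animal/plant split (1496 MY by
#' default), the Excavata protist outgroup attaches at the root (2230 MY),
#' and each clade is subdivided by a random coalescent process below its
#' crown age. Leaves are labelled `aNN` (animal), `pNN` (plant), `fNN`
#' (fungus), `eNN` (Excavata).
#'
#' @param config A [sim_config()]. Uses the current RNG state; call inside
#'   [simulate_dataset()] or after `set.seed()` for reproducibility.
#' @return List: `tree` (ultrametric `phylo`, branch lengths in MY),
#'   `species_table` (`species_id`, `clade_label`, `is_focal`), `newick`.
#' @export
simulate_species_tree <- function(config) {
  lbl <- list(
    animal = sprintf("a%02d", seq_len(config$n_animal)),
    plant = sprintf("p%02d", seq_len(config$n_plant)),
    fungus = sprintf("f%02d", seq_len(config$n_fungi)),
    excavata = sprintf("e%02d", seq_len(config$n_excavata))
  )
  an <- coalescent_newick(lbl$animal, config$crown_animal)
  fu <- coalescent_newick(lbl$fungus, config$crown_fungi)
  pl <- coalescent_newick(lbl$plant, config$crown_plant)
  ex <- coalescent_newick(lbl$excavata, config$crown_excavata)
  split_age <- config$strata$animal_plant_split
  root_age <- config$strata$feca_excavata_age
  opi <- sprintf("(%s:%.6f,%s:%.6f)", an$newick,
                 config$opisthokont_split - an$height,
                 fu$newick, config$opisthokont_split - fu$height)
  focal <- sprintf("(%s:%.6f,%s:%.6f)", opi,
                   split_age - config$opisthokont_split,
                   pl$newick, split_age - pl$height)
  full <- sprintf("(%s:%.6f,%s:%.6f);", focal, root_age - split_age,
                  ex$newick, root_age - ex$height)
  tree <- ape::read.tree(text = full)
  species_table <- tibble(
    species_id = c(lbl$animal, lbl$plant, lbl$fungus, lbl$excavata),
    clade_label = rep(c("animal", "plant", "fungus", "protist-excavata"),
                      times = c(config$n_animal, config$n_plant,
                                config$n_fungi, config$n_excavata)),
    is_focal = rep(c(TRUE, TRUE, TRUE, FALSE),
                   times = c(config$n_animal, config$n_plant,
                             config$n_fungi, config$n_excavata))
  )
  list(tree = tree, species_table = species_table, newick = full)
}

# tip indices below every node (postorder accumulation)
tips_below <- function(tree) {
  st <- dollo_structure(tree)
  res <- vector("list", st$nnode)
  for (i in seq_len(st$ntip)) res[[i]] <- i
  e <- st$edge
  for (i in seq_len(nrow(e))) {
    res[[e[i, 1]]] <- c(res[[e[i, 1]]], res[[e[i, 2]]])
  }
  lapply(res, sort)
}

# internal nodes whose tips all lie within `leaves` (candidate birth nodes)
clade_internal_nodes <- function(tree, leaves, tb = tips_below(tree)) {
  idx <- match(leaves, tree$tip.label)
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  internal[vapply(internal, function(v) {
    all(tb[[v]] %in% idx) && length(tb[[v]]) >= 2L
  }, logical(1))]
}
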