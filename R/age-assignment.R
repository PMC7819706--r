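#' Stratum configuration: calibration ages for ancient strata
#'
#' Calibration points, in millions of years (MY): the last universal common
#' ancestor (LUCA) at 4090 MY; domains born between LUCA and the emergence of
#' eukaryotes (2200 MY) dated at the halfway point 3145 MY; the first
#' eukaryotic common ancestor via the Excavata outgroup at 2230 MY; the last
#' eukaryotic common ancestor (LECA) at 2101 MY; and the divergence of plants
#' from animals/fungi at 1496 MY.
#'
#' @param luca_age,post_luca_age,feca_excavata_age,leca_age,animal_plant_split,eukaryote_emergence_age
#'   Ages in MY.
#' @return A list of class `stratum_config`.
#' @export
stratum_config <- function(luca_age = 4090, post_luca_age = 3145,
                           feca_excavata_age = 2230, leca_age = 2101,
                           animal_plant_split = 1496,
                           eukaryote_emergence_age = 2200) {
  cfg <- list(luca_age = luca_age, post_luca_age = post_luca_age,
              feca_excavata_age = feca_excavata_age, leca_age = leca_age,
              animal_plant_split = animal_plant_split,
              eukaryote_emergence_age = eukaryote_emergence_age)
  stopifnot(luca_age > post_luca_age, post_luca_age > feca_excavata_age,
            feca_excavata_age > leca_age, leca_age > animal_plant_split)
  if (abs(post_luca_age - (luca_age + eukaryote_emergence_age) / 2) > 1e-9) {
    abort("post_luca_age must be the midpoint of luca_age and eukaryote_emergence_age.")
  }
  structure(cfg, class = "stratum_config")
}

# ages (MY before present) for every node of an ultrametric tree
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  tip_depth <- depth[seq_len(ape::Ntip(tree))]
  max(tip_depth) - depth
}

is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depth)) <= tol * max(depth)
}

tree_parent <- function(tree, node) {
  hit <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(hit) == 0L) NA_integer_ else hit
}

#' Midpoint age of a pfam from its species presence
#'
#' A pfam is dated halfway between the most recent common ancestor (MRCA) of
#' the species carrying it and the node prior to that (the MRCA's parent).
#' A pfam observed in a single species takes the MRCA to be that leaf (age
#' 0), giving half the terminal branch's parent age. When the MRCA is the
#' root there is no prior node; the root's own age is returned with
#' attribute `at_root = TRUE`, and ancient-strata rules (see
#' [assign_ancient_stratum()]) normally take over upstream.
#'
#' @param tree An ultrametric `phylo` with branch lengths in MY.
#' @param presence Character vector of leaf names carrying the pfam.
#' @return Age in MY.
#' @export
pfam_mrca_age <- function(tree, presence) {
  presence <- unique(presence)
  if (length(presence) == 0L) abort("`presence` must be non-empty.")
  missing <- setdiff(presence, tree$tip.label)
  if (length(missing) > 0L) {
    abort(sprintf("Species not in tree: %s", paste(missing, collapse = ", ")))
  }
  ages <- node_ages(tree)
  root <- ape::Ntip(tree) + 1L
  if (length(presence) == 1L) {
    m <- match(presence, tree$tip.label)
  } else {
    m <- ape::getMRCA(tree, presence)
  }
  if (m == root) {
    return(structure(ages[root], at_root = TRUE))
  }
  parent <- tree_parent(tree, m)
  structure((ages[m] + ages[parent]) / 2, at_root = FALSE)
}

#' Ancient-stratum age from domain-of-life presence flags
#'
#' Pfams inferred present in LUCA are dated 4090 MY. Pfams found in
#' eukaryotes and bacteria but not archaea, or eukaryotes and archaea but
#' not bacteria — i.e. born after LUCA but before the emergence of
#' eukaryotes — are dated 3145 MY, the halfway point. Pfams annotated in all
#' three domains but absent from the LUCA list are also dated 3145 MY (the
#' LUCA list is the sole authority for the 4090 MY stratum). Eukaryote-only
#' pfams return `NA` and fall back to tree dating.
#'
#' @param in_eukaryotes,in_bacteria,in_archaea Logical presence flags.
#' @param pfam_id Pfam identifier, matched against `luca_pfams`.
#' @param luca_pfams Character vector of pfam ids inferred present in LUCA.
#' @param cfg A [stratum_config()].
#' @return Age in MY, or `NA` for eukaryote-only pfams.
#' @export
assign_ancient_stratum <- function(in_eukaryotes, in_bacteria, in_archaea,
                                   pfam_id, luca_pfams = character(0),
                                   cfg = stratum_config()) {
  if (!isTRUE(in_eukaryotes)) {
    abort("Pfam must be present in eukaryotes (the data set is eukaryotic).")
  }
  if (pfam_id %in% luca_pfams) return(cfg$luca_age)
  if (isTRUE(in_bacteria) || isTRUE(in_archaea)) return(cfg$post_luca_age)
  NA_real_
}

#' Gene age from its pfams' ages
#'
#' Genes are dated by their oldest pfam; genes without any retained pfam
#' must be excluded upstream.
#'
#' @param pfam_ages Non-empty numeric vector of ages in MY.
#' @return Maximum age in MY.
#' @export
gene_age <- function(pfam_ages) {
  if (length(pfam_ages) == 0L || all(is.na(pfam_ages))) {
    abort("Gene has no dated pfams; it should have been excluded upstream.")
  }
  max(pfam_ages, na.rm = TRUE)
}

#' Lineage tag for a dated pfam
#'
#' `ancient` for pfams older than the LECA (age > 2101 MY); `recent_animal`
#' (`recent_plant`) for pfams younger than the plant vs animal/fungi split
#' (age < 1496 MY) present in animal (plant) species, animal taking
#' precedence on (tree-impossible) joint presence; `intermediate` between
#' the two cutoffs; `other` otherwise (e.g. young fungus-only pfams).
#'
#' @param age Age in MY.
#' @param kingdoms Character vector of clade labels of the species carrying
#'   the pfam (`animal`, `plant`, `fungus`, `protist-excavata`, `other`).
#' @param cfg A [stratum_config()].
#' @return One of `"ancient"`, `"recent_animal"`, `"recent_plant"`,
#'   `"intermediate"`, `"other"`.
#' @export
lineage_tag <- function(age, kingdoms, cfg = stratum_config()) {
  if (age > cfg$leca_age) return("ancient")
  if (age < cfg$animal_plant_split) {
    if ("animal" %in% kingdoms) return("recent_animal")
    if ("plant" %in% kingdoms) return("recent_plant")
    return("other")
  }
  "intermediate"
}

#' Assign ages, age classes and lineage tags to all pfams
#'
#' Applies, in order: the LUCA list (4090 MY); the prokaryote-domain flags
#' (3145 MY); the Excavata rule (presence in non-protist eukaryotes plus at
#' least one Excavata species dates the pfam at the first-eukaryote stratum,
#' 2230 MY); otherwise the MRCA midpoint rule on the time tree. Protist
#' species are used only for dating, never as property datapoints.
#'
#' @param presence Tibble `pfam_id`, `species_id` (long form: one row per
#'   species carrying the pfam).
#' @param tree Ultrametric `phylo`, branch lengths in MY.
#' @param species_table Tibble `species_id`, `clade_label`, `is_focal`.
#' @param flags Optional tibble `pfam_id`, `in_bacteria`, `in_archaea`.
#' @param luca_pfams Character vector of LUCA pfam ids.
#' @param cfg A [stratum_config()].
#' @return Tibble `pfam_id`, `age_my`, `age_class`, `lineage_tag`,
#'   `n_species`; `age_class` identifiers (`PS01` = oldest) share one label
#'   per distinct assigned age.
#' @export
assign_ages <- function(presence, tree, species_table, flags = NULL,
                        luca_pfams = character(0), cfg = stratum_config()) {
  stopifnot(all(c("pfam_id", "species_id") %in% names(presence)))
  if (!is_ultrametric_tree(tree)) abort("`tree` must be ultrametric.")
  clade <- setNames(species_table$clade_label, species_table$species_id)
  missing <- setdiff(presence$species_id, tree$tip.label)
  if (length(missing) > 0L) {
    abort(sprintf("Species not in tree: %s", paste(unique(missing), collapse = ", ")))
  }
  fl <- tibble(pfam_id = unique(presence$pfam_id),
               in_bacteria = FALSE, in_archaea = FALSE)
  if (!is.null(flags)) {
    fl <- fl %>%
      select("pfam_id") %>%
      left_join(flags, by = "pfam_id") %>%
      mutate(in_bacteria = dplyr::coalesce(.data$in_bacteria, FALSE),
             in_archaea = dplyr::coalesce(.data$in_archaea, FALSE))
  }
  by_pfam <- presence %>%
    group_by(.data$pfam_id) %>%
    summarise(species = list(unique(.data$species_id)), .groups = "drop") %>%
    left_join(fl, by = "pfam_id")

  res <- purrr::pmap(by_pfam, function(pfam_id, species, in_bacteria, in_archaea) {
    age <- assign_ancient_stratum(TRUE, in_bacteria, in_archaea, pfam_id,
                                  luca_pfams, cfg)
    clades <- unname(clade[species])
    if (is.na(age)) {
      has_excavata <- any(clades == "protist-excavata")
      has_focal <- any(clades %in% c("animal", "plant", "fungus"))
      if (has_excavata && has_focal) {
        age <- cfg$feca_excavata_age
      } else {
        age <- as.numeric(pfam_mrca_age(tree, species))
      }
    }
    tibble(pfam_id = pfam_id, age_my = age,
           lineage_tag = lineage_tag(age, clades, cfg),
           n_species = length(species))
  })
  out <- bind_rows(res)
  rank <- match(out$age_my, sort(unique(out$age_my), decreasing = TRUE))
  out$age_class <- sprintf("PS%02d", rank)
  select(out, "pfam_id", "age_my", "age_class", "lineage_tag", "n_species")
}

#' Quantile summary of property values per age class
#'
#' One row per age class with the count, median, quartiles and the 9%/91%
#' quantiles (linear interpolation between order statistics) — the summary
#' behind width-weighted phylostratigraphy box plots. Classes with a single
#' datapoint are flagged.
#'
#' @param data Tibble with an age-class column and a value column.
#' @param class_col,value_col Column names (strings).
#' @return Tibble with `n`, `median`, `q25`, `q75`, `q09`, `q91`, `singleton`.
#' @export
age_class_summary <- function(data, class_col = "age_class", value_col = "value") {
  stopifnot(nrow(data) >= 1L)
  data %>%
    group_by(.data[[class_col]]) %>%
    summarise(n = sum(!is.na(.data[[value_col]])),
              median = median(.data[[value_col]], na.rm = TRUE),
              q25 = quantile(.data[[value_col]], 0.25, na.rm = TRUE, names = FALSE),
              q75 = quantile(.data[[value_col]], 0.75, na.rm = TRUE, names = FALSE),
              q09 = quantile(.data[[value_col]], 0.09, na.rm = TRUE, names = FALSE),
              q91 = quantile(.data[[value_col]], 0.91, na.rm = TRUE, names = FALSE),
              .groups = "drop") %>%
    mutate(singleton = .data$n == 1L)
}
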