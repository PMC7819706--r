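#' Run the full phylostratigraphy pipeline on a dataset
#'
#' Applies, in order: the pfam quality filters (annotation, keyword,
#' two-species, Dollo contamination test), removal of genes containing any
#' excluded pfam, age assignment on the time tree, transmembrane
#' classification, per-instance sequence metrics, per-pfam homology
#' datapoints (focal species only; protists date but never contribute
#' property values), and the headline phylostratigraphy slopes of mean
#' disorder and clustering over the standard non-transmembrane subsets.
#'
#' @param dataset A `phylostrat_sim` or the list returned by
#'   [read_dataset()].
#' @param n_reps Replicates for the Dollo null.
#' @param seed Seed for the Dollo null simulations.
#' @param apply_dollo Set `FALSE` to skip the contamination test (faster;
#'   annotation/keyword/two-species filters still run).
#' @return List of class `phylostrat_result`: `filter_report`, `ages`,
#'   `instances`, `datapoints` (non-TM and TM together; column `tm`),
#'   `slopes` (tidy slope table over subsets `all`, `ancient`,
#'   `recent_animal`, `recent_plant`).
#' @export
run_phylostrat <- function(dataset, n_reps = 1000L, seed = 1L,
                           apply_dollo = TRUE) {
  presence <- presence_from_annotations(dataset$annotations)
  if (apply_dollo) {
    report <- filter_pfams(dataset$metadata, presence, dataset$tree,
                           n_reps = n_reps, seed = seed)
  } else {
    report <- filter_pfams_no_dollo(dataset$metadata, presence)
  }
  kept <- report$pfam_id[report$stage_dropped == "kept"]
  ann <- filter(dataset$annotations, .data$pfam_id %in% kept)
  bad_genes <- genes_with_excluded_pfams(dataset$annotations, report)
  ann <- anti_join(ann, bad_genes, by = c("species_id", "gene_id"))
  presence_kept <- presence_from_annotations(ann)
  flags <- dataset$metadata %>%
    select("pfam_id", "in_bacteria", "in_archaea")
  ages <- assign_ages(presence_kept, dataset$tree, dataset$species_table,
                      flags = flags, luca_pfams = dataset$luca_pfams)
  tm <- classify_tm(ann, dataset$helices)
  metrics <- instance_metrics(dataset$proteins, ann,
                              disorder = dataset$disorder)
  inst <- metrics %>%
    left_join(tm$instances,
              by = c("species_id", "gene_id", "pfam_id", "start", "end")) %>%
    left_join(select(dataset$species_table, "species_id", "clade_label",
                     "is_focal"), by = "species_id")
  focal_inst <- filter(inst, .data$is_focal)
  datapoints <- pfam_datapoints(focal_inst, ages)
  slopes <- standard_slopes(datapoints)
  structure(list(filter_report = report, ages = ages, instances = inst,
                 datapoints = datapoints, slopes = slopes),
            class = "phylostrat_result")
}

# annotation + keyword + two-species stages only
filter_pfams_no_dollo <- function(metadata, presence) {
  pres <- presence %>%
    group_by(.data$pfam_id) %>%
    summarise(k = n_distinct(.data$species_id), .groups = "drop")
  meta <- metadata %>% left_join(pres, by = "pfam_id") %>%
    mutate(k = dplyr::coalesce(.data$k, 0L))
  rows <- purrr::pmap(meta, function(pfam_id, taxonomic_annotation,
                                     abstract_text, k, ...) {
    base <- tibble(pfam_id = pfam_id, stage_dropped = "kept",
                   reason = NA_character_, k = k,
                   observed_losses = NA_integer_, null_mean = NA_real_,
                   null_sd = NA_real_, z = NA_real_)
    af <- annotation_filter(taxonomic_annotation)
    if (!af$keep) {
      base$stage_dropped <- "annotation"; base$reason <- af$reason
      return(base)
    }
    kf <- keyword_filter(taxonomic_annotation, abstract_text)
    if (!kf$keep) {
      base$stage_dropped <- "keyword"; base$reason <- kf$reason
      return(base)
    }
    if (k < 2L) {
      base$stage_dropped <- "two_species"
      base$reason <- "fewer than two species"
    }
    base
  })
  bind_rows(rows)
}

# the headline disorder and clustering slopes over the standard
# non-transmembrane subsets
standard_slopes <- function(datapoints) {
  subsets <- list(
    all = quo(!.data$tm),
    ancient = quo(!.data$tm & .data$lineage_tag == "ancient"),
    recent_animal = quo(!.data$tm & .data$lineage_tag == "recent_animal"),
    recent_plant = quo(!.data$tm & .data$lineage_tag == "recent_plant")
  )
  rows <- purrr::imap(subsets, function(q, label) {
    purrr::map(c("mean_isd", "psi"), function(prop) {
      sl <- phylostrat_slope(datapoints, prop, subset = !!q, label = label)
      if (is.null(sl)) NULL else tidy(sl)
    })
  })
  bind_rows(purrr::flatten(rows))
}

#' Write pipeline results as TSV files
#'
#' Emits `filter_report.tsv`, `ages.tsv`, `datapoints.tsv`, `slopes.tsv`
#' into a directory.
#'
#' @param result A `phylostrat_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(sprintf("Cannot create directory '%s'.", dir))
  }
  readr::write_tsv(result$filter_report, file.path(dir, "filter_report.tsv"))
  readr::write_tsv(result$ages, file.path(dir, "ages.tsv"))
  readr::write_tsv(result$datapoints, file.path(dir, "datapoints.tsv"))
  readr::write_tsv(result$slopes, file.path(dir, "slopes.tsv"))
  invisible(dir)
}

#' @export
print.phylostrat_result <- function(x, ...) {
  kept <- sum(x$filter_report$stage_dropped == "kept")
  cat(sprintf("<phylostrat_result> %d/%d pfams kept, %d datapoints\n",
              kept, nrow(x$filter_report), nrow(x$datapoints)))
  print(x$slopes, n = nrow(x$slopes))
  invisible(x)
}
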