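#' Aggregate pfam instances into one homology datapoint
#'
#' Homologous instances share an evolutionary origin, so treating them as
#' independent datapoints is pseudoreplication; the unweighted mean across
#' all instances of a pfam (across all species carrying it) is treated as a
#' single datapoint instead. Undefined clustering values are excluded from
#' the psi mean, with the excluded count recorded.
#'
#' @param instances Tibble of metric rows for ONE key (see
#'   [instance_metrics()]), with `species_id` and metric columns.
#' @param scope `"all"`, or a clade label (with a `clade_label` column
#'   present) to average over e.g. only animal or only plant instances.
#' @return One-row tibble with `n_instances`, `n_species`, `tm` (majority
#'   rule), averaged metrics, and `psi_n_missing`.
#' @export
aggregate_pfam <- function(instances, scope = "all") {
  if (scope != "all") {
    stopifnot("clade_label" %in% names(instances))
    instances <- filter(instances, .data$clade_label == scope)
  }
  if (nrow(instances) == 0L) {
    return(tibble(n_instances = 0L))
  }
  metric_cols <- intersect(c("psi", "mean_isd", "mean_isd_noC", "length", AA_STANDARD),
                           names(instances))
  out <- instances %>%
    summarise(n_instances = n(),
              n_species = n_distinct(.data$species_id),
              psi_n_missing = sum(is.na(.data$psi)),
              tm = if ("tm" %in% names(instances)) mean(.data$tm) >= 0.5 else NA,
              across(dplyr::all_of(metric_cols),
                     ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)))
  out
}

#' Pfam co-occurrence links
#'
#' Two pfams A and B are linked when, over all protein-coding genes in the
#' data set, P(a gene has both | it has A or B) is at least 50%.
#'
#' @param gene_pfam Tibble `species_id`, `gene_id`, `pfam_id`.
#' @return Tibble `pfam_a`, `pfam_b` (a < b), `n_both`, `n_union`, `ratio`,
#'   `linked`; one row per pfam pair sharing at least one gene.
#' @export
cooccurrence_links <- function(gene_pfam) {
  gp <- gene_pfam %>%
    mutate(gene_key = paste(.data$species_id, .data$gene_id, sep = "|")) %>%
    distinct(.data$gene_key, .data$pfam_id)
  n_genes <- gp %>% count(.data$pfam_id, name = "n_genes")
  pairs <- gp %>%
    inner_join(gp, by = "gene_key", relationship = "many-to-many") %>%
    filter(.data$pfam_id.x < .data$pfam_id.y) %>%
    count(pfam_a = .data$pfam_id.x, pfam_b = .data$pfam_id.y, name = "n_both")
  pairs %>%
    left_join(rename(n_genes, n_a = "n_genes"), by = c(pfam_a = "pfam_id")) %>%
    left_join(rename(n_genes, n_b = "n_genes"), by = c(pfam_b = "pfam_id")) %>%
    mutate(n_union = .data$n_a + .data$n_b - .data$n_both,
           ratio = .data$n_both / .data$n_union,
           linked = 2L * .data$n_both >= .data$n_union) %>%
    select("pfam_a", "pfam_b", "n_both", "n_union", "ratio", "linked")
}

#' Whether two specific pfams are co-occurrence linked
#'
#' @param gene_pfam Tibble `species_id`, `gene_id`, `pfam_id`.
#' @param pfam_a,pfam_b Pfam ids.
#' @return Logical.
#' @export
cooccurrence_link <- function(gene_pfam, pfam_a, pfam_b) {
  gp <- gene_pfam %>%
    mutate(gene_key = paste(.data$species_id, .data$gene_id, sep = "|")) %>%
    distinct(.data$gene_key, .data$pfam_id)
  ga <- unique(gp$gene_key[gp$pfam_id == pfam_a])
  gb <- unique(gp$gene_key[gp$pfam_id == pfam_b])
  if (length(ga) == 0L || length(gb) == 0L) {
    abort("Both pfams must occur in at least one gene.")
  }
  n_both <- length(intersect(ga, gb))
  n_union <- length(union(ga, gb))
  2L * n_both >= n_union
}

#' Single-link homology groups from pfam links
#'
#' Connected components of the link graph; every pfam (linked or not)
#' receives a deterministic group id, the lexicographically smallest member.
#'
#' @param links Tibble with `pfam_a`, `pfam_b` and optionally `linked`
#'   (rows with `linked = FALSE` are ignored), e.g. from
#'   [cooccurrence_links()].
#' @param pfams Character vector of all pfam ids (to include singletons).
#' @return Tibble `pfam_id`, `group_id`.
#' @export
single_link_groups <- function(links, pfams = NULL) {
  if (!is.null(links) && nrow(links) > 0L && "linked" %in% names(links)) {
    links <- filter(links, .data$linked)
  }
  pfams <- sort(unique(c(pfams, links$pfam_a, links$pfam_b)))
  if (length(pfams) == 0L) {
    return(tibble(pfam_id = character(0), group_id = character(0)))
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(links) > 0L) links[, c("pfam_a", "pfam_b")] else
      tibble(pfam_a = character(0), pfam_b = character(0)),
    directed = FALSE,
    vertices = tibble(name = pfams)
  )
  comp <- igraph::components(g)$membership
  tibble(pfam_id = names(comp), membership = comp) %>%
    group_by(.data$membership) %>%
    mutate(group_id = min(.data$pfam_id)) %>%
    ungroup() %>%
    arrange(.data$pfam_id) %>%
    select("pfam_id", "group_id")
}

#' Homology key for a gene
#'
#' A gene is keyed by its single oldest pfam. When several pfams tie as
#' oldest, the gene is keyed by the single-link group containing them; ties
#' spanning different groups fall back to the smallest group id, with a
#' warning (the grouping is then ambiguous).
#'
#' @param pfam_ids Character vector of the gene's pfams.
#' @param pfam_ages Ages (MY) aligned with `pfam_ids`.
#' @param groups Tibble `pfam_id`, `group_id` from [single_link_groups()].
#' @return Single key string.
#' @export
gene_homology_key <- function(pfam_ids, pfam_ages, groups) {
  stopifnot(length(pfam_ids) >= 1L, length(pfam_ids) == length(pfam_ages))
  oldest <- pfam_ids[pfam_ages == max(pfam_ages)]
  if (length(oldest) == 1L) return(oldest)
  gid <- groups$group_id[match(oldest, groups$pfam_id)]
  gid[is.na(gid)] <- oldest[is.na(gid)]
  ug <- unique(gid)
  if (length(ug) > 1L) {
    warn(sprintf(
      "Equally-oldest pfams (%s) fall in different homology groups; using smallest id.",
      paste(oldest, collapse = ", ")))
  }
  min(ug)
}

#' Per-pfam homology datapoints
#'
#' Collapses instance metrics into one datapoint per pfam and joins the age
#' assignment, the unit entering every downstream regression.
#'
#' @param instances Output of [instance_metrics()], with a `tm` column (see
#'   [classify_tm()]) and optionally `clade_label` per species.
#' @param ages Output of [assign_ages()].
#' @param scope `"all"` or a clade label restricting which instances are
#'   averaged (the age assignment is unchanged).
#' @return Tibble: `key`, `key_type = "pfam"`, `n_instances`, `n_species`,
#'   `age_my`, `age_class`, `lineage_tag`, `tm`, metrics.
#' @export
pfam_datapoints <- function(instances, ages, scope = "all") {
  pts <- instances %>%
    group_by(key = .data$pfam_id) %>%
    dplyr::group_modify(~ aggregate_pfam(.x, scope = scope)) %>%
    ungroup() %>%
    filter(.data$n_instances > 0L) %>%
    mutate(key_type = "pfam")
  pts %>%
    inner_join(select(ages, -"n_species"), by = c(key = "pfam_id")) %>%
    select("key", "key_type", "n_instances", "n_species", "age_my",
           "age_class", "lineage_tag", "tm", dplyr::everything())
}

#' Per-gene-group homology datapoints
#'
#' Dates each gene by its oldest pfam, keys it by [gene_homology_key()], and
#' averages gene-level metrics over all genes sharing a key.
#'
#' @param gene_metrics Tibble of whole-gene metric rows (one per gene; e.g.
#'   [instance_metrics()] on full-gene intervals) with `species_id`,
#'   `gene_id` and metric columns.
#' @param annotations Tibble `species_id`, `gene_id`, `pfam_id` of retained
#'   pfams.
#' @param ages Output of [assign_ages()].
#' @param groups Output of [single_link_groups()].
#' @return Tibble keyed by gene homology id, with `age_my` = the oldest
#'   pfam age, metrics averaged across member genes.
#' @export
gene_datapoints <- function(gene_metrics, annotations, ages, groups) {
  ann <- annotations %>%
    inner_join(select(ages, "pfam_id", "age_my"), by = "pfam_id")
  keys <- ann %>%
    group_by(.data$species_id, .data$gene_id) %>%
    summarise(key = gene_homology_key(.data$pfam_id, .data$age_my, groups),
              age_my = gene_age(.data$age_my), .groups = "drop")
  dat <- inner_join(gene_metrics, keys, by = c("species_id", "gene_id"))
  dat %>%
    group_by(.data$key) %>%
    dplyr::group_modify(function(d, g) {
      agg <- aggregate_pfam(d)
      agg$age_my <- d$age_my[1]
      agg
    }) %>%
    ungroup() %>%
    mutate(key_type = "gene_group") %>%
    select("key", "key_type", "age_my", dplyr::everything())
}
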