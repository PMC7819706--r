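# --- gene assembly ------------------------------------------------------------

# pair a fraction of first-eukaryote pfams into shared two-domain genes
domain_pairs <- function(histories, config) {
  feca <- histories$pfam_id[histories$stratum == "feca"]
  npairs <- min(floor(config$multi_domain_frac * length(feca)),
                length(feca) %/% 2L)
  if (npairs == 0L) {
    return(tibble(pfam_a = character(0), pfam_b = character(0)))
  }
  chosen <- sample(feca, 2L * npairs)
  tibble(pfam_a = chosen[seq_len(npairs)],
         pfam_b = chosen[npairs + seq_len(npairs)])
}

# build genes (linker + domain(s) + linker) and interval annotations
assemble_genes <- function(instances, histories, config) {
  pairs <- domain_pairs(histories, config)
  inst <- instances
  inst$gene_id <- paste0("g_", inst$pfam_id)
  if (nrow(pairs) > 0L) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$pfam_a[i]; b <- pairs$pfam_b[i]
      sa <- inst$species_id[inst$pfam_id == a]
      sb <- inst$species_id[inst$pfam_id == b]
      shared <- intersect(sa, sb)
      gid <- paste0("g_", a, "_", b)
      sel <- inst$pfam_id %in% c(a, b) & inst$species_id %in% shared
      inst$gene_id[sel] <- gid
    }
  }
  base_probs <- config$baseline_composition
  genes <- inst %>%
    arrange(.data$species_id, .data$gene_id, .data$pfam_id) %>%
    group_by(.data$species_id, .data$gene_id) %>%
    summarise(pfams = list(.data$pfam_id), seqs = list(.data$sequence),
              .groups = "drop")
  ng <- nrow(genes)
  k_per <- lengths(genes$pfams)
  n_link <- sum(k_per) + ng
  link_len <- sample(15:30, n_link, replace = TRUE)
  link_letters <- iid_letters(sum(link_len), base_probs)
  link_seq <- vapply(split(link_letters, rep(seq_len(n_link), link_len)),
                     paste, character(1), collapse = "")
  link_off <- cumsum(c(0L, k_per + 1L))
  gene_seq <- character(ng)
  ann_sp <- ann_gene <- ann_pfam <- vector("list", ng)
  ann_start <- ann_end <- vector("list", ng)
  for (g in seq_len(ng)) {
    segs <- genes$seqs[[g]]
    k <- k_per[g]
    linkers <- link_seq[(link_off[g] + 1L):(link_off[g] + k + 1L)]
    pieces <- character(2L * k + 1L)
    pieces[seq(1L, 2L * k + 1L, by = 2L)] <- linkers
    pieces[seq(2L, 2L * k, by = 2L)] <- segs
    gene_seq[g] <- paste(pieces, collapse = "")
    seg_len <- nchar(segs)
    lk_len <- nchar(linkers)
    starts <- cumsum(lk_len[seq_len(k)]) +
      cumsum(c(0L, seg_len[-k][seq_len(k - 1L)])) + 1L
    ann_sp[[g]] <- rep(genes$species_id[g], k)
    ann_gene[[g]] <- rep(genes$gene_id[g], k)
    ann_pfam[[g]] <- genes$pfams[[g]]
    ann_start[[g]] <- starts
    ann_end[[g]] <- starts + seg_len - 1L
  }
  list(proteins = tibble(species_id = genes$species_id,
                         gene_id = genes$gene_id, sequence = gene_seq),
       annotations = tibble(species_id = unlist(ann_sp),
                            gene_id = unlist(ann_gene),
                            pfam_id = unlist(ann_pfam),
                            start = unlist(ann_start),
                            end = unlist(ann_end)))
}

# per-residue disorder scores per gene: propensity (monotone in local
# hydrophilicity) plus any direct per-lineage age shift on pfam intervals,
# smoothed with the surrogate's moving-average window
score_disorder <- function(proteins, annotations, histories, config) {
  prop_tab <- default_disorder_propensity(config$disorder_lo, config$disorder_hi)
  shift_by_pfam <- setNames(
    ifelse(is.na(histories$true_age_my), 0,
           config$disorder_slope[histories$lineage] *
             histories$true_age_my / 1000),
    histories$pfam_id)
  shift_by_pfam[is.na(shift_by_pfam)] <- 0
  any_shift <- any(shift_by_pfam != 0)
  ann <- split(annotations, paste(annotations$species_id, annotations$gene_id, sep = "|"))
  scores <- vector("list", nrow(proteins))
  for (g in seq_len(nrow(proteins))) {
    res <- strsplit(proteins$sequence[g], "", fixed = TRUE)[[1]]
    prop <- as.numeric(prop_tab[res])
    if (any_shift) {
      key <- paste(proteins$species_id[g], proteins$gene_id[g], sep = "|")
      a <- ann[[key]]
      if (!is.null(a)) {
        for (i in seq_len(nrow(a))) {
          sh <- shift_by_pfam[[a$pfam_id[i]]]
          if (sh != 0) {
            idx <- a$start[i]:a$end[i]
            prop[idx] <- prop[idx] + sh
          }
        }
      }
      prop <- pmin(pmax(prop, 0), 1)
    }
    scores[[g]] <- running_mean(prop, config$disorder_window)
  }
  tibble(species_id = proteins$species_id, gene_id = proteins$gene_id,
         scores = scores)
}

# transmembrane helices: each instance of a TM-designated pfam gets one
# 21-residue helix inside its interval
make_helices <- function(annotations, tm_pfams, config) {
  sel <- annotations %>% filter(.data$pfam_id %in% tm_pfams)
  if (nrow(sel) == 0L) {
    return(tibble(species_id = character(0), gene_id = character(0),
                  helix_start = integer(0), helix_end = integer(0)))
  }
  hel_len <- 21L
  off <- vapply(seq_len(nrow(sel)), function(i) {
    span <- sel$end[i] - sel$start[i] + 1L - hel_len
    if (span <= 0L) 0L else sample.int(span + 1L, 1L) - 1L
  }, integer(1))
  tibble(species_id = sel$species_id, gene_id = sel$gene_id,
         helix_start = sel$start + off,
         helix_end = pmin(sel$start + off + hel_len - 1L, sel$end))
}

# --- metadata and filter decoys ----------------------------------------------

benign_abstract_shared <- "Ancient enzymatic domain conserved in all organisms."
benign_abstract_euk <- "Conserved catalytic domain of eukaryotic proteins."

make_metadata <- function(histories, config) {
  shared <- histories$in_bacteria | histories$in_archaea | histories$is_luca
  tibble(pfam_id = histories$pfam_id,
         taxonomic_annotation = if_else(shared, "shared_with_prokaryotes",
                                        "eukaryote_only"),
         abstract_text = if_else(shared, benign_abstract_shared,
                                 benign_abstract_euk),
         in_bacteria = histories$in_bacteria,
         in_archaea = histories$in_archaea)
}

# decoy pfams whose metadata exercises each stage of the keyword /
# annotation filters; `expected_stage` records the stage meant to fire
make_filter_decoys <- function(tree, species_table, config, start_index = 1L) {
  counts <- config$n_filter_decoys
  types <- rep(names(counts), times = counts)
  if (length(types) == 0L) {
    return(list(histories = tibble(pfam_id = character(0)),
                metadata = tibble(pfam_id = character(0)),
                expected = tibble(pfam_id = character(0),
                                  decoy_type = character(0),
                                  expected_stage = character(0))))
  }
  tb <- tips_below(tree)
  root <- ape::Ntip(tree) + 1L
  st <- config$strata
  rows <- meta <- exp_rows <- vector("list", length(types))
  for (j in seq_along(types)) {
    ty <- types[j]
    id <- sprintf("DY%03d", start_index + j - 1L)
    surv <- apply_losses(tree, root, config$loss_rate, tb)
    if (length(surv) < 2L) surv <- tb[[root]]
    shared <- ty %in% c("no_abstract", "viral", "rescued", "prokaryote_only")
    rows[[j]] <- tibble(
      pfam_id = id, stratum = paste0("decoy_", ty), lineage = "ancient",
      true_age_my = if (shared) st$post_luca_age else st$feca_excavata_age,
      birth_node = root, in_bacteria = shared, in_archaea = FALSE,
      is_luca = FALSE, n_losses = length(tb[[root]]) - length(surv),
      presence = list(tree$tip.label[surv]))
    meta[[j]] <- switch(ty,
      prokaryote_only = tibble(pfam_id = id,
        taxonomic_annotation = "prokaryote_only",
        abstract_text = "Cell wall anchoring domain."),
      unannotated = tibble(pfam_id = id,
        taxonomic_annotation = "unannotated",
        abstract_text = benign_abstract_euk),
      no_abstract = tibble(pfam_id = id,
        taxonomic_annotation = "shared_with_prokaryotes",
        abstract_text = NA_character_),
      organelle = tibble(pfam_id = id,
        taxonomic_annotation = "eukaryote_only",
        abstract_text = "Membrane domain targeted to the chloroplast."),
      viral = tibble(pfam_id = id,
        taxonomic_annotation = "shared_with_prokaryotes",
        abstract_text = "Viral capsid assembly domain."),
      rescued = tibble(pfam_id = id,
        taxonomic_annotation = "shared_with_prokaryotes",
        abstract_text = "Domain of bacterial origin with yeast and human homologs."))
    meta[[j]]$in_bacteria <- shared
    meta[[j]]$in_archaea <- FALSE
    exp_rows[[j]] <- tibble(pfam_id = id, decoy_type = ty,
                            expected_stage = switch(ty,
                              prokaryote_only = "annotation",
                              unannotated = "annotation",
                              no_abstract = "keyword",
                              organelle = "keyword",
                              viral = "keyword",
                              rescued = "kept"))
  }
  list(histories = bind_rows(rows), metadata = bind_rows(meta),
       expected = bind_rows(exp_rows))
}

# --- whole-dataset orchestration ---------------------------------------------

#' Simulate a complete synthetic phylostratigraphy dataset
#'
#' Generates, from one seed, every input the pipeline consumes: the species
#' tree, pfam histories with planted lineage-specific composition/disorder
#' trends and a universal clustering trend, contaminants, filter decoys,
#' gene sequences with interval annotations, transmembrane helices,
#' per-residue disorder scores, pfam metadata and the LUCA list — plus a
#' truth table for recovery checks.
#'
#' @param config A [sim_config()].
#' @return List of class `phylostrat_sim`: `tree`, `newick`,
#'   `species_table`, `proteins`, `annotations`, `helices`, `disorder`,
#'   `metadata`, `luca_pfams`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  tr <- simulate_species_tree(config)
  hist <- simulate_pfam_histories(tr$tree, tr$species_table, config)
  decoys <- make_filter_decoys(tr$tree, tr$species_table, config,
                               start_index = 1L)
  cont <- inject_contaminants(tr$tree, config, start_index = 1L)
  all_hist <- bind_rows(hist, decoys$histories, cont)
  seqs <- simulate_sequences(all_hist, config)
  genes <- assemble_genes(seqs$instances, all_hist, config)
  n_trend <- nrow(hist)
  tm_pfams <- sample(hist$pfam_id, floor(config$tm_frac * n_trend))
  helices <- make_helices(genes$annotations, tm_pfams, config)
  disorder <- score_disorder(genes$proteins, genes$annotations, all_hist, config)
  metadata <- bind_rows(
    make_metadata(bind_rows(hist, cont), config),
    decoys$metadata
  )
  truth <- all_hist %>%
    mutate(n_species = lengths(.data$presence),
           contaminant = .data$stratum == "contaminant") %>%
    select("pfam_id", "stratum", "lineage", "true_age_my", "birth_node",
           "n_losses", "n_species", "contaminant") %>%
    left_join(select(seqs$pfam_params, "pfam_id", "target_h", "target_psi"),
              by = "pfam_id") %>%
    left_join(decoys$expected, by = "pfam_id") %>%
    mutate(decoy_type = dplyr::coalesce(.data$decoy_type, "none"),
           expected_stage = dplyr::coalesce(
             .data$expected_stage,
             if_else(.data$contaminant, "dollo", "kept")),
           is_tm = .data$pfam_id %in% tm_pfams)
  structure(list(tree = tr$tree, newick = tr$newick,
                 species_table = tr$species_table,
                 proteins = genes$proteins, annotations = genes$annotations,
                 helices = helices, disorder = disorder, metadata = metadata,
                 luca_pfams = hist$pfam_id[hist$is_luca], truth = truth,
                 config = config),
            class = "phylostrat_sim")
}

#' @export
print.phylostrat_sim <- function(x, ...) {
  cat(sprintf(
    "<phylostrat_sim> %d species, %d pfams (%d contaminants, %d decoys), %d genes, seed %d\n",
    nrow(x$species_table), nrow(x$truth), sum(x$truth$contaminant),
    sum(x$truth$decoy_type != "none"),
    nrow(x$proteins), x$config$seed))
  invisible(x)
}

#' Species presence table implied by the annotations
#'
#' @param annotations Tibble with `pfam_id`, `species_id`.
#' @return Distinct tibble `pfam_id`, `species_id`.
#' @export
presence_from_annotations <- function(annotations) {
  distinct(annotations, .data$pfam_id, .data$species_id)
}

# --- on-disk round trip -------------------------------------------------------

#' Write a synthetic dataset to disk
#'
#' Emits the exact file formats the pipeline consumes: `tree.nwk`,
#' `species_table.tsv`, `proteins.fasta` (headers `species_id|gene_id`),
#' `pfam_annotations.tsv`, `pfam_metadata.tsv`, `tm_helices.tsv`,
#' `disorder_scores.tsv` (long: one row per residue), `luca_pfams.txt`,
#' `truth.tsv`. Same seed, same bytes.
#'
#' @param sim A `phylostrat_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(sprintf("Cannot create directory '%s'.", dir))
  }
  writeLines(sim$newick, file.path(dir, "tree.nwk"))
  readr::write_tsv(sim$species_table, file.path(dir, "species_table.tsv"))
  seqs <- Biostrings::AAStringSet(setNames(
    sim$proteins$sequence,
    paste(sim$proteins$species_id, sim$proteins$gene_id, sep = "|")))
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteins.fasta"))
  readr::write_tsv(sim$annotations, file.path(dir, "pfam_annotations.tsv"))
  readr::write_tsv(sim$metadata, file.path(dir, "pfam_metadata.tsv"))
  readr::write_tsv(sim$helices, file.path(dir, "tm_helices.tsv"))
  disorder_long <- sim$disorder %>%
    mutate(position = purrr::map(.data$scores, seq_along)) %>%
    tidyr::unnest(c("position", "scores")) %>%
    select("species_id", "gene_id", "position", score = "scores")
  readr::write_tsv(disorder_long, file.path(dir, "disorder_scores.tsv"))
  writeLines(sim$luca_pfams, file.path(dir, "luca_pfams.txt"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a dataset directory back into memory
#'
#' @param dir Directory written by [write_dataset()] (or hand-assembled in
#'   the same formats; `truth.tsv` is optional).
#' @return List with the same components as [simulate_dataset()] (minus
#'   `config`; `truth` only if present on disk).
#' @export
read_dataset <- function(dir) {
  newick <- readLines(file.path(dir, "tree.nwk"))
  tree <- ape::read.tree(text = paste(newick, collapse = ""))
  species_table <- readr::read_tsv(file.path(dir, "species_table.tsv"),
                                   show_col_types = FALSE)
  fa <- Biostrings::readAAStringSet(file.path(dir, "proteins.fasta"))
  hdr <- strsplit(names(fa), "|", fixed = TRUE)
  proteins <- tibble(species_id = vapply(hdr, `[`, character(1), 1L),
                     gene_id = vapply(hdr, `[`, character(1), 2L),
                     sequence = unname(as.character(fa)))
  annotations <- readr::read_tsv(file.path(dir, "pfam_annotations.tsv"),
                                 show_col_types = FALSE)
  metadata <- readr::read_tsv(file.path(dir, "pfam_metadata.tsv"),
                              show_col_types = FALSE)
  helices <- readr::read_tsv(file.path(dir, "tm_helices.tsv"),
                             show_col_types = FALSE)
  disorder <- readr::read_tsv(file.path(dir, "disorder_scores.tsv"),
                              show_col_types = FALSE) %>%
    arrange(.data$species_id, .data$gene_id, .data$position) %>%
    group_by(.data$species_id, .data$gene_id) %>%
    summarise(scores = list(.data$score), .groups = "drop")
  luca <- readLines(file.path(dir, "luca_pfams.txt"))
  luca <- luca[nzchar(luca)]
  out <- list(tree = tree, newick = paste(newick, collapse = ""),
              species_table = species_table, proteins = proteins,
              annotations = annotations, helices = helices,
              disorder = disorder, metadata = metadata, luca_pfams = luca)
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    out$truth <- readr::read_tsv(truth_path, show_col_types = FALSE)
  }
  out
}
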