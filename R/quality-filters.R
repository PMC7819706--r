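#' Annotation-based pfam filter
#'
#' Drops pfams annotated as occurring in prokaryotes but not eukaryotes
#' (likely contamination or horizontal transfer when seen in a eukaryotic
#' data set) and pfams without any species annotation.
#'
#' @param taxonomic_annotation One of `eukaryote_only`,
#'   `shared_with_prokaryotes`, `prokaryote_only`, `unannotated`.
#' @return List `keep` (logical), `reason` (string or `NA`).
#' @export
annotation_filter <- function(taxonomic_annotation) {
  switch(taxonomic_annotation,
    prokaryote_only = list(keep = FALSE, reason = "prokaryote-annotated"),
    unannotated = list(keep = FALSE, reason = "no species annotation"),
    eukaryote_only = ,
    shared_with_prokaryotes = list(keep = TRUE, reason = NA_character_),
    abort(sprintf("Unknown taxonomic annotation '%s'.", taxonomic_annotation))
  )
}

keyword_exclude_patterns <- function() {
  c("viral", "virus", "bacter", "capsid", "bacillus", "pilus", "pilin",
    "mitochondria", "chloroplast")
}

keyword_rescue_patterns <- function() {
  c("eukary", "vertebrat", "fung", "metazoa", "plant", "mammal", "insect",
    "yeast", "human", "all organisms", "antibod", "immune")
}

matches_any <- function(text, patterns) {
  text <- tolower(text)
  any(vapply(patterns, function(p) grepl(p, text, fixed = TRUE), logical(1)))
}

#' Keyword-based pfam filter on abstract text
#'
#' Pfams without an abstract are dropped. Eukaryote-only pfams are dropped
#' when the abstract mentions mitochondria or chloroplast (organellar
#' history distorts dating). Pfams shared with prokaryotes are dropped when
#' the abstract matches any exclusion term (viral, virus, bacter*, capsid,
#' bacillus, pilus, pilin, mitochondria, chloroplast) unless rescued by a
#' eukaryote-context term (eukary*, vertebrat, fung*, metazoa, plant,
#' mammal, insect, yeast, human, all organisms, antibod, immune). Matching
#' is case-insensitive substring search; trailing `*` in the lists above
#' denotes the prefix already covered by substring semantics.
#'
#' @param taxonomic_annotation As in [annotation_filter()]; must be a kept
#'   category.
#' @param abstract_text Free text or `NA`.
#' @return List `keep`, `reason`.
#' @export
keyword_filter <- function(taxonomic_annotation, abstract_text) {
  if (is.na(abstract_text) || !nzchar(abstract_text)) {
    return(list(keep = FALSE, reason = "no abstract"))
  }
  if (taxonomic_annotation == "eukaryote_only") {
    if (matches_any(abstract_text, c("mitochondria", "chloroplast"))) {
      return(list(keep = FALSE, reason = "organelle term"))
    }
    return(list(keep = TRUE, reason = NA_character_))
  }
  if (matches_any(abstract_text, keyword_exclude_patterns()) &&
      !matches_any(abstract_text, keyword_rescue_patterns())) {
    return(list(keep = FALSE, reason = "prokaryote/viral term"))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Two-species quality filter
#'
#' Pfams present in fewer than two species are dropped, excluding non-genic
#' contaminants supported by a single genome.
#'
#' @param presence Character vector of species carrying the pfam.
#' @return `TRUE` to keep.
#' @export
two_species_filter <- function(presence) {
  length(unique(presence)) >= 2L
}

# precomputed traversal structure reused across many Dollo evaluations
dollo_structure <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, ntip = ape::Ntip(tree),
       nnode = ape::Ntip(tree) + tree$Nnode, tips = tree$tip.label)
}

dollo_losses_core <- function(st, tip_has) {
  cnt <- integer(st$nnode)
  cnt[seq_len(st$ntip)] <- as.integer(tip_has)
  ep <- st$edge[, 1]; ec <- st$edge[, 2]
  for (i in seq_along(ep)) cnt[ep[i]] <- cnt[ep[i]] + cnt[ec[i]]
  k <- sum(tip_has)
  cand <- which(cnt == k)
  # the MRCA is the candidate with the smallest subtree
  size <- integer(st$nnode)
  size[seq_len(st$ntip)] <- 1L
  for (i in seq_along(ep)) size[ep[i]] <- size[ep[i]] + size[ec[i]]
  m <- cand[which.min(size[cand])]
  in_sub <- logical(st$nnode)
  in_sub[m] <- TRUE
  for (i in rev(seq_along(ep))) if (in_sub[ep[i]]) in_sub[ec[i]] <- TRUE
  sum(in_sub[ep] & cnt[ec] == 0L & cnt[ep] > 0L)
}

#' Dollo-parsimony loss count
#'
#' Under single-origin (Dollo) parsimony the pfam is gained once at the MRCA
#' of the species carrying it; the inferred number of losses is the number
#' of maximal subtrees below that MRCA containing no carrier species.
#'
#' @param tree A `phylo`.
#' @param presence Character vector of carrier leaf names (non-empty).
#' @return Integer loss count.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' dollo_losses(tr, c("A", "C"))  # 2
#' @export
dollo_losses <- function(tree, presence) {
  presence <- unique(presence)
  if (length(presence) == 0L) abort("`presence` must be non-empty.")
  missing <- setdiff(presence, tree$tip.label)
  if (length(missing) > 0L) {
    abort(sprintf("Species not in tree: %s", paste(missing, collapse = ", ")))
  }
  st <- dollo_structure(tree)
  dollo_losses_core(st, st$tips %in% presence)
}

#' Monte-Carlo null distribution of Dollo losses
#'
#' Simulates the loss count expected if `k` carrier species were chosen
#' uniformly at random (without replacement) — the signature of random
#' contamination rather than shared descent.
#'
#' @param tree A `phylo`.
#' @param k Number of carrier species.
#' @param n_reps Replicates (>= 100).
#' @param seed Optional integer seed (local to this call).
#' @return List `k`, `n_reps`, `mean`, `sd`, `losses` (replicate counts).
#' @export
dollo_null <- function(tree, k, n_reps = 1000L, seed = NULL) {
  stopifnot(n_reps >= 100L, k >= 1L, k <= ape::Ntip(tree))
  st <- dollo_structure(tree)
  losses <- local_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      tip_has <- logical(st$ntip)
      tip_has[sample.int(st$ntip, k)] <- TRUE
      dollo_losses_core(st, tip_has)
    }, integer(1))
  })
  list(k = k, n_reps = n_reps, mean = mean(losses), sd = sd(losses),
       losses = losses)
}

#' Random-contamination z-test for a pfam's phylogenetic distribution
#'
#' Compares the observed Dollo loss count against the Monte-Carlo null of
#' [dollo_null()]. A phylogenetically coherent pfam needs far fewer losses
#' than a random scatter, giving a strongly negative z-score; pfams with
#' z > -2 are indistinguishable from random contamination and rejected. The
#' test applies only to pfams found in less than half the species; more
#' widespread pfams are kept untested.
#'
#' @param tree A `phylo`.
#' @param presence Carrier leaf names.
#' @param n_reps Null replicates.
#' @param seed Optional seed for the null simulation.
#' @param null Optional precomputed [dollo_null()] for this `k` (nulls are
#'   cached per species count and reused across pfams).
#' @return A list of class `dollo_test` with `pfam_id` (optional), `k`,
#'   `observed_losses`, `null_mean`, `null_sd`, `z`, `tested`, `rejected`,
#'   `n_reps`, `note`.
#' @export
contamination_test <- function(tree, presence, n_reps = 1000L, seed = NULL,
                               null = NULL) {
  presence <- unique(presence)
  S <- ape::Ntip(tree)
  k <- length(presence)
  out <- list(k = k, observed_losses = NA_integer_, null_mean = NA_real_,
              null_sd = NA_real_, z = NA_real_, tested = FALSE,
              rejected = FALSE, n_reps = n_reps, note = NA_character_)
  class(out) <- "dollo_test"
  if (k >= ceiling(S / 2)) {
    out$note <- "not tested (present in at least half the species), kept"
    return(out)
  }
  obs <- dollo_losses(tree, presence)
  if (is.null(null)) null <- dollo_null(tree, k, n_reps, seed)
  stopifnot(null$k == k)
  out$observed_losses <- obs
  out$null_mean <- null$mean
  out$null_sd <- null$sd
  out$tested <- TRUE
  if (is.na(null$sd) || null$sd == 0) {
    warn("Null distribution of losses is degenerate (sd = 0); pfam kept.")
    out$tested <- FALSE
    out$note <- "degenerate null, kept"
    return(out)
  }
  out$z <- (obs - null$mean) / null$sd
  out$rejected <- out$z > -2
  out
}

#' @export
print.dollo_test <- function(x, ...) {
  if (!x$tested) {
    cat(sprintf("<dollo_test> k = %d: %s\n", x$k, x$note))
  } else {
    cat(sprintf("<dollo_test> k = %d, losses = %d, null %.2f +/- %.2f, z = %.2f -> %s\n",
                x$k, x$observed_losses, x$null_mean, x$null_sd, x$z,
                if (x$rejected) "rejected" else "kept"))
  }
  invisible(x)
}

#' Full pfam exclusion pipeline
#'
#' Applies, in order: the annotation filter, the keyword filter, the
#' two-species filter, and the Dollo-parsimony contamination test (one
#' cached null per species count `k`). Each stage is a pure predicate, so
#' the surviving set is order-independent; the recorded `stage_dropped` is
#' simply the first stage to fire.
#'
#' @param metadata Tibble `pfam_id`, `taxonomic_annotation`, `abstract_text`.
#' @param presence Tibble `pfam_id`, `species_id`.
#' @param tree A `phylo` covering the presence species.
#' @param n_reps Null replicates for the contamination test.
#' @param seed Integer seed for the null simulations.
#' @return Tibble `pfam_id`, `stage_dropped` (`"kept"` or the stage name),
#'   `reason`, `k`, `observed_losses`, `null_mean`, `null_sd`, `z`.
#' @export
filter_pfams <- function(metadata, presence, tree, n_reps = 1000L, seed = 1L) {
  stopifnot(all(c("pfam_id", "taxonomic_annotation", "abstract_text") %in% names(metadata)))
  pres <- presence %>%
    group_by(.data$pfam_id) %>%
    summarise(species = list(unique(.data$species_id)), .groups = "drop")
  meta <- metadata %>% left_join(pres, by = "pfam_id")
  null_cache <- new.env(parent = emptyenv())
  rows <- purrr::pmap(meta, function(pfam_id, taxonomic_annotation,
                                     abstract_text, species = NULL, ...) {
    base <- tibble(pfam_id = pfam_id, stage_dropped = "kept",
                   reason = NA_character_,
                   k = length(species %||% character(0)),
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
    if (is.null(species) || !two_species_filter(species)) {
      base$stage_dropped <- "two_species"
      base$reason <- "fewer than two species"
      return(base)
    }
    k <- length(species)
    key <- as.character(k)
    if (is.null(null_cache[[key]]) && k < ceiling(ape::Ntip(tree) / 2)) {
      null_cache[[key]] <- dollo_null(tree, k, n_reps, seed = seed + k)
    }
    dt <- contamination_test(tree, species, n_reps, null = null_cache[[key]])
    base$observed_losses <- dt$observed_losses
    base$null_mean <- dt$null_mean
    base$null_sd <- dt$null_sd
    base$z <- dt$z
    if (dt$tested && dt$rejected) {
      base$stage_dropped <- "dollo"
      base$reason <- "indistinguishable from random contamination"
    }
    base
  })
  bind_rows(rows)
}

#' Genes contaminated by an excluded pfam
#'
#' All genes containing any excluded pfam are themselves removed from
#' downstream analyses.
#'
#' @param annotations Tibble `species_id`, `gene_id`, `pfam_id`.
#' @param filter_report Output of [filter_pfams()].
#' @return Tibble of `species_id`, `gene_id` to drop.
#' @export
genes_with_excluded_pfams <- function(annotations, filter_report) {
  bad <- filter_report$pfam_id[filter_report$stage_dropped != "kept"]
  annotations %>%
    filter(.data$pfam_id %in% bad) %>%
    distinct(.data$species_id, .data$gene_id)
}

local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
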