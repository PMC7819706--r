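# --- pfam birth/loss histories -----------------------------------------------

# survivors (tip indices) below `node` after a Poisson loss process on branches
apply_losses <- function(tree, node, rate, tb) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  if (rate <= 0) return(tb[[node]])
  edge <- tree$edge
  len <- tree$edge.length
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  surv <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (ei in kids[[as.character(v)]]) {
      lost <- runif(1) < 1 - exp(-rate * len[ei] / 100)
      if (lost) next
      child <- edge[ei, 2]
      if (child <= ntip) surv <- c(surv, child) else stack <- c(stack, child)
    }
  }
  sort(surv)
}

#' Simulate pfam birth/loss histories on the species tree
#'
#' Each pfam is assigned a birth node according to its stratum: LUCA,
#' post-LUCA and first-eukaryote pfams at the root; `basal` pfams at the
#' crown of the focal (animal+fungi+plant) clade; `recent_*` pfams at a
#' random internal node of the respective clade. Losses fall on descendant
#' branches as a Poisson process at `loss_rate` per 100 MY; a loss removes
#' the whole subtree. Histories leaving fewer than two surviving species
#' are redrawn. The recorded true age is the age the dating rules assign to
#' the loss-free history (stratum constants, or the MRCA midpoint).
#'
#' @param tree,species_table From [simulate_species_tree()].
#' @param config A [sim_config()].
#' @return Tibble: `pfam_id`, `stratum`, `lineage`, `true_age_my`,
#'   `birth_node`, `in_bacteria`, `in_archaea`, `is_luca`, `n_losses`
#'   (count of redraws-free loss events), `presence` (list of species ids).
#' @export
simulate_pfam_histories <- function(tree, species_table, config) {
  tb <- tips_below(tree)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  focal_leaves <- species_table$species_id[species_table$is_focal]
  focal_crown <- ape::getMRCA(tree, focal_leaves)
  clade_nodes <- list(
    animal = clade_internal_nodes(tree, species_table$species_id[species_table$clade_label == "animal"], tb),
    plant = clade_internal_nodes(tree, species_table$species_id[species_table$clade_label == "plant"], tb),
    fungi = clade_internal_nodes(tree, species_table$species_id[species_table$clade_label == "fungus"], tb)
  )
  midpoint_age <- function(node) {
    parent <- tree_parent(tree, node)
    if (is.na(parent)) ages[node] else (ages[node] + ages[parent]) / 2
  }
  counts <- config$pfam_counts
  specs <- list()
  add <- function(stratum, n, lineage, node_pool, age_fun, in_b, in_a, luca) {
    if (n <= 0L) return()
    specs[[length(specs) + 1L]] <<- tibble(
      stratum = stratum, lineage = lineage, n = n,
      node_pool = list(node_pool), age_fun = list(age_fun),
      in_bacteria = in_b, in_archaea = in_a, is_luca = luca)
  }
  st <- config$strata
  add("luca", counts[["luca"]], "ancient", root,
      function(node) st$luca_age, TRUE, TRUE, TRUE)
  add("post_luca", counts[["post_luca"]], "ancient", root,
      function(node) st$post_luca_age, NA, NA, FALSE)  # flags drawn per pfam
  add("feca", counts[["feca"]], "ancient", root,
      function(node) st$feca_excavata_age, FALSE, FALSE, FALSE)
  add("basal", counts[["basal"]], "ancient", focal_crown,
      midpoint_age, FALSE, FALSE, FALSE)
  add("recent_animal", counts[["recent_animal"]], "animal",
      clade_nodes$animal, midpoint_age, FALSE, FALSE, FALSE)
  add("recent_plant", counts[["recent_plant"]], "plant",
      clade_nodes$plant, midpoint_age, FALSE, FALSE, FALSE)
  add("recent_fungi", counts[["recent_fungi"]], "fungi",
      clade_nodes$fungi, midpoint_age, FALSE, FALSE, FALSE)

  n_total <- sum(vapply(specs, function(s) as.integer(s$n), integer(1)))
  out <- list(stratum = character(n_total), lineage = character(n_total),
              true_age_my = numeric(n_total), birth_node = integer(n_total),
              in_bacteria = logical(n_total), in_archaea = logical(n_total),
              is_luca = logical(n_total), n_losses = integer(n_total),
              presence = vector("list", n_total))
  idx <- 0L
  for (sp in specs) {
    pool <- sp$node_pool[[1]]
    age_fun <- sp$age_fun[[1]]
    for (j in seq_len(sp$n)) {
      idx <- idx + 1L
      node <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
      surv <- apply_losses(tree, node, config$loss_rate, tb)
      tries <- 0L
      while (length(surv) < 2L && tries < 50L) {
        surv <- apply_losses(tree, node, config$loss_rate, tb)
        tries <- tries + 1L
      }
      if (length(surv) < 2L) surv <- tb[[node]]
      in_b <- sp$in_bacteria
      in_a <- sp$in_archaea
      if (is.na(in_b)) {  # post-LUCA: bacteria-only or archaea-only presence
        in_b <- runif(1) < 0.5
        in_a <- !in_b
      }
      out$stratum[idx] <- sp$stratum
      out$lineage[idx] <- sp$lineage
      out$true_age_my[idx] <- age_fun(node)
      out$birth_node[idx] <- node
      out$in_bacteria[idx] <- in_b
      out$in_archaea[idx] <- in_a
      out$is_luca[idx] <- sp$is_luca
      out$n_losses[idx] <- length(tb[[node]]) - length(surv)
      out$presence[[idx]] <- tree$tip.label[surv]
    }
  }
  bind_cols(tibble(pfam_id = sprintf("PF%05d", seq_len(n_total))),
            as_tibble(out))
}

#' Inject random-presence contaminant pfams
#'
#' Contaminants have no birth node: their carrier sets are drawn uniformly
#' at random from all species (sparsity below half the species count), the
#' signature the Dollo contamination test is built to reject. Their
#' sequences carry baseline composition and no age trend.
#'
#' @param tree A `phylo`.
#' @param config A [sim_config()].
#' @param start_index First integer for pfam ids.
#' @return Tibble shaped like [simulate_pfam_histories()] output with
#'   `stratum = "contaminant"`, `true_age_my = NA`.
#' @export
inject_contaminants <- function(tree, config, start_index = 1L) {
  n <- config$n_contaminants
  if (n == 0L) {
    return(tibble(pfam_id = character(0)))
  }
  S <- ape::Ntip(tree)
  kr <- pmin(config$contaminant_k, floor((S - 1) / 2))
  rows <- purrr::map(seq_len(n), function(j) {
    k <- sample(seq(kr[1], kr[2]), 1L)
    tibble(pfam_id = sprintf("CN%05d", start_index + j - 1L),
           stratum = "contaminant", lineage = "ancient",
           true_age_my = NA_real_, birth_node = NA_integer_,
           in_bacteria = FALSE, in_archaea = FALSE, is_luca = FALSE,
           n_losses = NA_integer_,
           presence = list(sort(sample(tree$tip.label, k))))
  })
  bind_rows(rows)
}

# --- clustering calibration ---------------------------------------------------

.psi_map_cache <- new.env(parent = emptyenv())

# two-state Markov arrangements: TRUE = hydrophobic; one row per instance
simulate_arrangements <- function(lens, h, lam) {
  n <- length(lens)
  Lmax <- max(lens)
  h <- rep_len(h, n)
  lam <- rep_len(lam, n)
  pHH <- pmin(pmax(h + lam * (1 - h), 0), 1)
  pPH <- pmin(pmax(h * (1 - lam), 0), 1)
  states <- matrix(FALSE, n, Lmax)
  states[, 1] <- runif(n) < h
  if (Lmax > 1L) {
    for (j in 2:Lmax) {
      p <- ifelse(states[, j - 1L], pHH, pPH)
      states[, j] <- runif(n) < p
    }
  }
  states
}

#' Calibration map between Markov persistence and expected clustering
#'
#' The generator plants clustering via the arrangement of hydrophobic
#' residues (a two-state Markov chain), not via composition, so composition
#' and clustering trends stay independently controllable. This map links
#' the chain's persistence parameter to the expected clustering index by
#' simulation on a fixed internal seed (cached per parameter set): mean psi
#' is estimated on a persistence grid, smoothed with a cubic fit, and
#' inverted.
#'
#' @param h Hydrophobic fraction used for calibration.
#' @param length_range Instance length range (residues).
#' @param block_size Clustering block size.
#' @param grid Persistence grid (0 = independent arrangement).
#' @param reps Simulated sequences per grid point.
#' @return List: `psi_to_lambda(psi)` vectorized inverse map, `grid`,
#'   `mean_psi`, `psi_range`.
#' @export
psi_lambda_map <- function(h, length_range, block_size = 6L,
                           grid = seq(0, 0.9, by = 0.05), reps = 800L) {
  key <- paste(round(h, 4), paste(length_range, collapse = "-"), block_size,
               paste(range(grid), collapse = "-"), length(grid), reps,
               sep = "|")
  cached <- .psi_map_cache[[key]]
  if (!is.null(cached)) return(cached)
  mean_psi <- local_seed(204061L, {
    vapply(grid, function(lam) {
      lens <- sample(seq(length_range[1], length_range[2]), reps, replace = TRUE)
      states <- simulate_arrangements(lens, h, lam)
      mean(vapply(seq_len(reps), function(i) {
        e <- ifelse(states[i, seq_len(lens[i])], 1L, -1L)
        clustering_index(e, block_size)$psi
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  })
  fit <- lm(mean_psi ~ poly(grid, 3, raw = TRUE))
  lam_fine <- seq(min(grid), max(grid), by = 0.002)
  psi_fine <- cummax(as.numeric(predict(fit, newdata = data.frame(grid = lam_fine))))
  map <- list(
    psi_to_lambda = function(psi) {
      approx(psi_fine, lam_fine,
             xout = pmin(pmax(psi, min(psi_fine)), max(psi_fine)),
             rule = 2, ties = "ordered")$y
    },
    grid = grid, mean_psi = mean_psi, psi_range = range(psi_fine))
  .psi_map_cache[[key]] <- map
  map
}

# --- sequence simulation ------------------------------------------------------

# split baseline into hydrophobic / hydrophilic letter distributions
split_composition <- function(baseline) {
  hyd <- baseline[AA_HYDROPHOBIC]
  phi <- baseline[setdiff(AA_STANDARD, AA_HYDROPHOBIC)]
  list(h_frac = sum(hyd), hyd = hyd / sum(hyd), phi = phi / sum(phi))
}

iid_letters <- function(n, probs) {
  if (n == 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate per-instance pfam sequences with planted trends
#'
#' Draws, for every (pfam, carrier species) instance, an amino-acid
#' sequence whose hydrophobic fraction matches the pfam's age- and
#' lineage-dependent target in expectation, whose hydrophobic residues are
#' arranged by a two-state Markov chain tuned (via [psi_lambda_map()]) to
#' the pfam's target clustering index, and per-residue disorder
#' propensities that are monotone in local hydrophilicity.
#'
#' @param histories Tibble from [simulate_pfam_histories()] (optionally with
#'   contaminant rows appended).
#' @param config A [sim_config()].
#' @return List: `pfam_params` (per-pfam targets) and `instances` (tibble
#'   `pfam_id`, `species_id`, `length`, `sequence`, `target_h`,
#'   `target_psi`).
#' @export
simulate_sequences <- function(histories, config) {
  base <- split_composition(config$baseline_composition)
  map <- psi_lambda_map(base$h_frac, config$length_range)
  n_pfam <- nrow(histories)
  age_by <- ifelse(is.na(histories$true_age_my), 0, histories$true_age_my / 1000)
  slope_h <- config$hydrophobic_slope[histories$lineage]
  slope_h[is.na(slope_h)] <- 0
  contaminant <- histories$stratum == "contaminant"
  ancient <- histories$lineage == "ancient" & !contaminant
  drift <- ifelse(contaminant, 0,
                  slope_h * age_by +
                    ifelse(ancient, config$ancient_hydrophobic_offset %||% 0, 0))
  target_h <- base$h_frac + drift + rnorm(n_pfam, 0, config$pfam_jitter_h)
  target_h <- pmin(pmax(target_h, 0.08), 0.65)
  target_psi <- ifelse(contaminant, 1,
                       config$clustering_intercept +
                         config$clustering_slope * age_by) +
    rnorm(n_pfam, 0, config$pfam_jitter_psi)
  target_psi <- pmin(pmax(target_psi, map$psi_range[1]), map$psi_range[2])
  lambda <- map$psi_to_lambda(target_psi)
  # per-pfam within-group composition jitter (lognormal, renormalized)
  jit <- config$pfam_jitter_comp
  hyd_w <- lapply(seq_len(n_pfam), function(i) {
    w <- base$hyd * exp(rnorm(6, 0, jit)); w / sum(w)
  })
  phi_w <- lapply(seq_len(n_pfam), function(i) {
    w <- base$phi * exp(rnorm(14, 0, jit)); w / sum(w)
  })
  pfam_params <- tibble(pfam_id = histories$pfam_id,
                        target_h = target_h, target_psi = target_psi,
                        lambda = lambda, hyd_w = hyd_w, phi_w = phi_w)
  inst <- histories %>%
    select("pfam_id", "presence") %>%
    tidyr::unnest(presence) %>%
    rename(species_id = "presence")
  inst$length <- sample(seq(config$length_range[1], config$length_range[2]),
                        nrow(inst), replace = TRUE)
  ord <- match(inst$pfam_id, pfam_params$pfam_id)
  states <- simulate_arrangements(inst$length, target_h[ord], lambda[ord])
  seqs <- character(nrow(inst))
  for (i in seq_len(n_pfam)) {
    rows <- which(ord == i)
    if (length(rows) == 0L) next
    res_list <- lapply(rows, function(r) states[r, seq_len(inst$length[r])])
    all_states <- unlist(res_list)
    letters <- character(length(all_states))
    letters[all_states] <- iid_letters(sum(all_states), hyd_w[[i]])
    letters[!all_states] <- iid_letters(sum(!all_states), phi_w[[i]])
    offs <- cumsum(c(0L, lengths(res_list)))
    for (j in seq_along(rows)) {
      seqs[rows[j]] <- paste(letters[(offs[j] + 1L):offs[j + 1L]], collapse = "")
    }
  }
  inst$sequence <- seqs
  inst$target_h <- target_h[ord]
  inst$target_psi <- target_psi[ord]
  list(pfam_params = pfam_params, instances = inst)
}
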