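test_that("simulated species trees are ultrametric, labelled, and reproducible", {
  cfg <- sim_config(seed = 5, n_animal = 4, n_plant = 4, n_fungi = 2,
                    n_excavata = 2)
  set.seed(cfg$seed)
  tr1 <- simulate_species_tree(cfg)
  set.seed(cfg$seed)
  tr2 <- simulate_species_tree(cfg)
  expect_identical(tr1$newick, tr2$newick)
  expect_equal(ape::Ntip(tr1$tree), 12L)
  # ultrametric: every leaf at the same depth, equal to the root age
  depths <- ape::node.depth.edgelength(tr1$tree)[1:12]
  expect_equal(max(abs(depths - 2230)), 0, tolerance = 1e-6)
  expect_equal(sum(tr1$species_table$clade_label == "animal"), 4L)
  expect_false(any(tr1$species_table$is_focal[
    tr1$species_table$clade_label == "protist-excavata"]))
})

test_that("a zero loss rate leaves the whole birth clade present", {
  cfg <- sim_config(seed = 6, loss_rate = 0, n_animal = 6, n_plant = 4,
                    n_fungi = 2, n_excavata = 2,
                    pfam_counts = c(luca = 2, post_luca = 2, feca = 2,
                                    basal = 2, recent_animal = 6,
                                    recent_plant = 2, recent_fungi = 2))
  set.seed(cfg$seed)
  tr <- simulate_species_tree(cfg)
  hist <- simulate_pfam_histories(tr$tree, tr$species_table, cfg)
  tb <- phylotrends:::tips_below(tr$tree)
  for (i in seq_len(nrow(hist))) {
    expect_setequal(hist$presence[[i]],
                    tr$tree$tip.label[tb[[hist$birth_node[i]]]])
    expect_equal(hist$n_losses[i], 0L)
  }
  # root-born strata carry the printed calibration ages as truth
  expect_true(all(hist$true_age_my[hist$stratum == "luca"] == 4090))
  expect_true(all(hist$true_age_my[hist$stratum == "post_luca"] == 3145))
  expect_true(all(hist$true_age_my[hist$stratum == "feca"] == 2230))
  # post-LUCA pfams are annotated in exactly one prokaryote domain
  pl <- hist[hist$stratum == "post_luca", ]
  expect_true(all(xor(pl$in_bacteria, pl$in_archaea)))
})

test_that("independent arrangements average a clustering index of one", {
  set.seed(23)
  st <- phylotrends:::simulate_arrangements(rep(120L, 800), h = 1 / 3, lam = 0)
  psis <- apply(st, 1, function(s) clustering_index(ifelse(s, 1L, -1L))$psi)
  expect_equal(mean(psis, na.rm = TRUE), 1, tolerance = 0.05)
  # persistent arrangements cluster well above one
  stp <- phylotrends:::simulate_arrangements(rep(120L, 400), h = 1 / 3, lam = 0.6)
  psip <- apply(stp, 1, function(s) clustering_index(ifelse(s, 1L, -1L))$psi)
  expect_gt(mean(psip, na.rm = TRUE), 1.5)
})

test_that("the persistence map is monotone and inverts the target psi", {
  cfg <- sim_config()
  base <- phylotrends:::split_composition(cfg$baseline_composition)
  map <- psi_lambda_map(base$h_frac, cfg$length_range)
  expect_true(all(diff(map$mean_psi) > -0.05))  # monotone up to noise
  expect_lt(abs(map$psi_to_lambda(1) - 0), 0.05)
  expect_gt(map$psi_to_lambda(1.6), map$psi_to_lambda(1.2))
})

test_that("generated sequences hit their target composition in expectation", {
  cfg <- sim_config(seed = 9, pfam_jitter_h = 0, pfam_jitter_comp = 0,
                    length_range = c(150L, 150L))
  set.seed(1)
  hist <- tibble::tibble(
    pfam_id = "PF1", stratum = "feca", lineage = "ancient",
    true_age_my = 2230, birth_node = NA_integer_, in_bacteria = FALSE,
    in_archaea = FALSE, is_luca = FALSE, n_losses = 0L,
    presence = list(sprintf("s%02d", 1:70)))
  seqs <- simulate_sequences(hist, cfg)
  big <- paste(seqs$instances$sequence, collapse = "")  # 10,500 residues
  comp <- composition(big)$fractions
  h_obs <- sum(comp[c("L", "I", "V", "F", "M", "W")])
  h_target <- seqs$pfam_params$target_h[1]
  expect_equal(h_obs, h_target, tolerance = 3 * sqrt(0.25 / nchar(big)) /
                 h_target)
  # within-group proportions follow the baseline split
  base <- phylotrends:::split_composition(cfg$baseline_composition)
  expect_equal(unname(comp[c("L", "I", "V", "F", "M", "W")] / h_obs),
               unname(base$hyd), tolerance = 0.05)
})

test_that("contaminant injection marks truth and respects sparsity", {
  cfg <- small_full_config(11)
  sim <- simulate_dataset(cfg)
  cont <- sim$truth[sim$truth$contaminant, ]
  expect_equal(nrow(cont), cfg$n_contaminants)
  expect_true(all(startsWith(cont$pfam_id, "CN")))
  expect_true(all(is.na(cont$true_age_my)))
  expect_true(all(cont$n_species >= cfg$contaminant_k[1] &
                    cont$n_species < ape::Ntip(sim$tree) / 2))
  none <- simulate_dataset(sim_config(seed = 2, n_contaminants = 0,
                                      pfam_counts = c(luca = 2, post_luca = 2,
                                                      feca = 2, basal = 2,
                                                      recent_animal = 4,
                                                      recent_plant = 2,
                                                      recent_fungi = 2)))
  expect_equal(sum(none$truth$contaminant), 0L)
})

test_that("truth and emitted files are mutually consistent", {
  sim <- simulate_dataset(small_full_config(13))
  ann_pfams <- unique(sim$annotations$pfam_id)
  expect_setequal(ann_pfams, sim$truth$pfam_id)
  expect_setequal(unique(sim$metadata$pfam_id), sim$truth$pfam_id)
  # every annotation has a sequence and an in-range interval
  joined <- dplyr::inner_join(sim$annotations, sim$proteins,
                              by = c("species_id", "gene_id"))
  expect_equal(nrow(joined), nrow(sim$annotations))
  expect_true(all(joined$end <= nchar(joined$sequence)))
  # disorder profiles cover every gene at full length
  dis <- dplyr::inner_join(sim$proteins, sim$disorder,
                           by = c("species_id", "gene_id"))
  expect_equal(nrow(dis), nrow(sim$proteins))
  expect_true(all(lengths(dis$scores) == nchar(dis$sequence)))
  expect_true(all(unlist(dis$scores) >= 0 & unlist(dis$scores) <= 1))
})

test_that("datasets round-trip through disk byte-identically and re-aggregate", {
  sim <- simulate_dataset(sim_config(
    seed = 17, n_animal = 4, n_plant = 4, n_fungi = 2, n_excavata = 2,
    pfam_counts = c(luca = 2, post_luca = 2, feca = 3, basal = 2,
                    recent_animal = 6, recent_plant = 3, recent_fungi = 2),
    n_contaminants = 2,
    n_filter_decoys = c(prokaryote_only = 1, unannotated = 1, no_abstract = 1,
                        organelle = 1, viral = 1, rescued = 1)))
  d1 <- file.path(tempdir(), "ds1")
  d2 <- file.path(tempdir(), "ds2")
  write_dataset(sim, d1)
  write_dataset(sim, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  back <- read_dataset(d1)
  expect_identical(sort(back$tree$tip.label), sort(sim$tree$tip.label))
  expect_identical(back$proteins$sequence[order(back$proteins$gene_id)],
                   sim$proteins$sequence[order(sim$proteins$gene_id)])
  # metrics computed from the read-back dataset match the in-memory ones
  m1 <- instance_metrics(sim$proteins, sim$annotations, sim$disorder)
  m2 <- instance_metrics(back$proteins, back$annotations, back$disorder)
  ord <- function(m) m[order(m$species_id, m$gene_id, m$pfam_id, m$start), ]
  m1 <- ord(m1); m2 <- ord(m2)
  expect_equal(m2$psi, m1$psi)
  expect_equal(m2$mean_isd, m1$mean_isd, tolerance = 1e-12)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("YAML configurations round-trip into sim_config", {
  path <- file.path(tempdir(), "sim.yaml")
  writeLines(c("seed: 42", "n_animal: 6", "loss_rate: 0.005",
               "pfam_counts:", "  luca: 3", "  post_luca: 3", "  feca: 3",
               "  basal: 3", "  recent_animal: 5", "  recent_plant: 3",
               "  recent_fungi: 2"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$n_animal, 6)
  expect_equal(cfg$loss_rate, 0.005)
  expect_equal(cfg$pfam_counts[["recent_animal"]], 5)
  writeLines("not_a_key: 1", path)
  expect_error(read_sim_config(path), "Unknown config keys")
  unlink(path)
})
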