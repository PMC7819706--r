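# shared fixtures: small trees and reduced simulation configurations

# ((A,B) at 100, parent at 200, C at 200) ... root at 300
toy_tree <- function() {
  ape::read.tree(text = "(((A:100,B:100):100,C:200):100,D:300);")
}

quartet_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# perfectly balanced ultrametric tree with 2^depth leaves, unit branches
balanced_tree <- function(depth) {
  nw <- sprintf("t%d:1", seq_len(2^depth))
  for (d in seq_len(depth)) {
    nw <- vapply(seq_len(length(nw) / 2), function(i) {
      sprintf("(%s,%s):1", nw[2 * i - 1], nw[2 * i])
    }, character(1))
  }
  ape::read.tree(text = sub(":1$", ";", nw))
}

# unbalanced (caterpillar) ultrametric tree with n leaves
caterpillar_tree <- function(n) {
  nw <- "t1:1"
  for (i in 2:n) {
    nw <- sprintf("(%s,t%d:%d):1", nw, i, i - 1)
  }
  ape::read.tree(text = sub(":1$", ";", nw))
}

# a small tree with labelled clades and an Excavata outgroup, plus its
# species table, for age-assignment tests
labelled_tree <- function() {
  nw <- paste0("((((a1:300,a2:300):805,(f1:400,f2:400):705):391,",
               "(p1:500,p2:500):996):734,(e1:900,e2:900):1330);")
  tree <- ape::read.tree(text = nw)
  species <- tibble::tibble(
    species_id = c("a1", "a2", "f1", "f2", "p1", "p2", "e1", "e2"),
    clade_label = c("animal", "animal", "fungus", "fungus",
                    "plant", "plant", "protist-excavata", "protist-excavata"),
    is_focal = c(rep(TRUE, 6), FALSE, FALSE))
  list(tree = tree, species_table = species)
}

# reduced-scale configuration for recovery experiments
recovery_config <- function(seed) {
  sim_config(
    seed = seed, n_animal = 10, n_plant = 6, n_fungi = 4, n_excavata = 2,
    pfam_counts = c(luca = 10, post_luca = 10, feca = 15, basal = 15,
                    recent_animal = 60, recent_plant = 30, recent_fungi = 0),
    n_contaminants = 0,
    n_filter_decoys = c(prokaryote_only = 0, unannotated = 0,
                        no_abstract = 0, organelle = 0, viral = 0,
                        rescued = 0))
}

# small complete configuration exercising every component
small_full_config <- function(seed) {
  sim_config(
    seed = seed, n_animal = 8, n_plant = 6, n_fungi = 4, n_excavata = 2,
    pfam_counts = c(luca = 8, post_luca = 10, feca = 12, basal = 10,
                    recent_animal = 40, recent_plant = 20, recent_fungi = 6),
    n_contaminants = 8,
    n_filter_decoys = c(prokaryote_only = 2, unannotated = 2,
                        no_abstract = 2, organelle = 2, viral = 2,
                        rescued = 2))
}

hydrophobic_fraction <- function(datapoints) {
  rowSums(as.matrix(datapoints[, c("L", "I", "V", "F", "M", "W")]))
}
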