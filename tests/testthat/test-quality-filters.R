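test_that("annotation filter drops prokaryote-annotated and unannotated pfams", {
  expect_false(annotation_filter("prokaryote_only")$keep)
  expect_match(annotation_filter("prokaryote_only")$reason, "prokaryote")
  expect_false(annotation_filter("unannotated")$keep)
  expect_true(annotation_filter("eukaryote_only")$keep)
  expect_true(annotation_filter("shared_with_prokaryotes")$keep)
  expect_error(annotation_filter("weird"), "Unknown")
})

test_that("keyword filter applies exclusion and rescue term lists", {
  kf <- function(ann, txt) keyword_filter(ann, txt)$keep
  # shared pfams: excluded unless rescued
  expect_false(kf("shared_with_prokaryotes", "a viral capsid protein"))
  expect_true(kf("shared_with_prokaryotes", "bacterial and yeast homologs"))
  expect_false(kf("shared_with_prokaryotes", "Bacterium-specific pilin"))
  expect_true(kf("shared_with_prokaryotes", "found in all organisms"))
  expect_true(kf("shared_with_prokaryotes", "a generic enzymatic domain"))
  # case-insensitive substring with prefix-wildcard semantics
  expect_false(kf("shared_with_prokaryotes", "BACTERIAL cell wall"))
  expect_true(kf("shared_with_prokaryotes", "bacterial protein of Fungal origin"))
  # eukaryote-only pfams: organelle terms only
  expect_false(kf("eukaryote_only", "imported into the chloroplast"))
  expect_false(kf("eukaryote_only", "Mitochondrial carrier"))
  expect_true(kf("eukaryote_only", "a viral-like fold"))  # no organelle term
  # missing abstract is always dropped
  expect_false(kf("shared_with_prokaryotes", NA))
  expect_false(kf("eukaryote_only", ""))
  expect_match(keyword_filter("eukaryote_only", NA)$reason, "abstract")
})

test_that("two-species filter drops singletons only", {
  expect_false(two_species_filter("sp1"))
  expect_true(two_species_filter(c("sp1", "sp2")))
  expect_false(two_species_filter(c("sp1", "sp1")))
  expect_true(two_species_filter(sprintf("sp%d", 1:435)))
})

test_that("Dollo losses count maximal absent subtrees under the MRCA", {
  tr <- quartet_tree()
  expect_equal(dollo_losses(tr, c("A", "B", "C", "D")), 0L)
  expect_equal(dollo_losses(tr, "A"), 0L)
  expect_equal(dollo_losses(tr, c("A", "C")), 2L)
  expect_equal(dollo_losses(tr, c("A", "B")), 0L)
  expect_equal(dollo_losses(tr, c("A", "B", "C")), 1L)
  expect_error(dollo_losses(tr, "nope"), "nope")
})

test_that("Dollo losses match the exhaustive single-gain oracle on small trees", {
  trees <- list(quartet_tree(), balanced_tree(2), caterpillar_tree(5),
                ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:2,f:2):1);"))
  for (tr in trees) {
    tabs <- oracle_dollo_tables(tr)
    tips <- tr$tip.label
    n <- length(tips)
    for (code in seq_len(2^n - 1)) {
      pres <- tips[bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) > 0]
      expect_equal(dollo_losses(tr, pres), oracle_dollo(tr, pres, tabs),
                   info = paste(pres, collapse = ","))
    }
  }
})

test_that("contamination test keeps coherent pfams and rejects random scatter", {
  tr <- balanced_tree(5)  # 32 leaves
  # an entire 8-leaf clade: far fewer losses than random
  clade <- tr$tip.label[1:8]
  res <- contamination_test(tr, clade, n_reps = 500, seed = 99)
  expect_true(res$tested)
  expect_equal(res$observed_losses, 0L)
  expect_lte(res$z, -2)
  expect_false(res$rejected)
  # uniform scatter: losses near the null mean
  set.seed(100)
  scatter <- sample(tr$tip.label, 8)
  res2 <- contamination_test(tr, scatter, n_reps = 500, seed = 99)
  expect_gt(res2$z, -2)
  expect_true(res2$rejected)
})

test_that("pfams in at least half the species are kept untested", {
  tr <- balanced_tree(6)  # 64 leaves
  res <- contamination_test(tr, tr$tip.label[1:40], n_reps = 100)
  expect_false(res$tested)
  expect_false(res$rejected)
  expect_match(res$note, "not tested")
  # boundary: 32 of 64 is not less than half
  res32 <- contamination_test(tr, tr$tip.label[seq(1, 63, 2)], n_reps = 100)
  expect_false(res32$tested)
})

test_that("degenerate nulls are flagged and kept", {
  tr <- quartet_tree()
  expect_warning(res <- contamination_test(tr, "A", n_reps = 100, seed = 4),
                 "degenerate")
  expect_false(res$rejected)
})

test_that("null loss mean grows with carrier count away from the half-species boundary", {
  tr <- balanced_tree(5)
  means <- vapply(c(2, 4, 6, 8, 10, 12), function(k) {
    dollo_null(tr, k, n_reps = 400, seed = 123 + k)$mean
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("the staged filter report matches the individual predicates", {
  tr <- balanced_tree(4)
  tips <- tr$tip.label
  metadata <- tibble::tibble(
    pfam_id = c("P_keep", "P_prok", "P_noann", "P_virus", "P_resc",
                "P_org", "P_single", "P_noabs"),
    taxonomic_annotation = c("eukaryote_only", "prokaryote_only",
                             "unannotated", "shared_with_prokaryotes",
                             "shared_with_prokaryotes", "eukaryote_only",
                             "eukaryote_only", "shared_with_prokaryotes"),
    abstract_text = c("a standard domain", "anything", "anything",
                      "viral capsid", "bacterial with human homologs",
                      "chloroplast import", "a standard domain", NA))
  presence <- tibble::tibble(
    pfam_id = c(rep("P_keep", 4), rep("P_virus", 4), rep("P_resc", 4),
                "P_single", rep("P_prok", 2), rep("P_noann", 2),
                rep("P_org", 2), rep("P_noabs", 2)),
    species_id = c(tips[1:4], tips[1:4], tips[5:8], tips[1],
                   tips[1:2], tips[1:2], tips[1:2], tips[1:2]))
  report <- filter_pfams(metadata, presence, tr, n_reps = 200, seed = 5)
  stage <- setNames(report$stage_dropped, report$pfam_id)
  expect_equal(stage[["P_keep"]], "kept")
  expect_equal(stage[["P_prok"]], "annotation")
  expect_equal(stage[["P_noann"]], "annotation")
  expect_equal(stage[["P_virus"]], "keyword")
  expect_equal(stage[["P_org"]], "keyword")
  expect_equal(stage[["P_noabs"]], "keyword")
  expect_equal(stage[["P_single"]], "two_species")
  expect_true(stage[["P_resc"]] %in% c("kept", "dollo"))
  # z-scores are reported for Dollo-tested pfams
  expect_false(is.na(report$z[report$pfam_id == "P_keep"]))
  # genes carrying any excluded pfam are dropped
  ann <- tibble::tibble(species_id = tips[1],
                        gene_id = c("g1", "g1", "g2"),
                        pfam_id = c("P_keep", "P_virus", "P_keep"))
  bad <- genes_with_excluded_pfams(ann, report)
  expect_equal(bad$gene_id, "g1")
})
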