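test_that("hydrophobicity encoding scores every residue class correctly", {
  expect_equal(unname(hydrophobicity_encode("LIVFMW")), rep(1L, 6))
  expect_equal(unname(hydrophobicity_encode("ACDE")), rep(-1L, 4))
  expect_equal(unname(hydrophobicity_encode("BJZUO")),
               c(-1L, 1L, -1L, -1L, -1L))
  expect_equal(unname(hydrophobicity_encode("X")), -1L)
  expect_equal(unname(hydrophobicity_encode("livf")), rep(1L, 4))
  expect_error(hydrophobicity_encode("AC1E"), "position 3")
  expect_error(hydrophobicity_encode(""), "non-empty")
})

test_that("clustering index reproduces hand-evaluated values", {
  expect_equal(clustering_index("LLLLLLAAAAAA")$psi, 11.0)
  expect_equal(clustering_index("LLLAAALLLAAA")$psi, 0.0)
  # intermediate normalizer for the fully separated arrangement
  res <- clustering_index("LLLLLLAAAAAA")
  expect_equal(res$per_frame_normalizers, 36 / 11)
  expect_equal(res$per_frame_totals, 0)
  expect_equal(res$n_frames, 1L)
})

test_that("frame handling follows p = L mod block size with tail truncation", {
  # L = 14 -> p = 2 frames, truncated to N = 12
  res <- clustering_index(strrep("LA", 7))
  expect_equal(res$n_frames, 2L)
  expect_equal(res$truncated_length, 12L)
  expect_equal(res$psi, mean(res$per_frame_psi))
  # L = 12 -> exactly one frame
  expect_equal(clustering_index(strrep("LA", 6))$n_frames, 1L)
})

test_that("degenerate sequences yield undefined clustering, not errors", {
  short <- clustering_index("LALALA")  # L = 6 < 2s
  expect_false(short$defined)
  expect_identical(short$reason, "too short")
  expect_true(is.na(short$psi))
  onesign <- clustering_index(strrep("L", 18))
  expect_false(onesign$defined)
  expect_identical(onesign$reason, "single-sign frame")
})

test_that("mean psi over all distinct arrangements of a composition is exactly 1", {
  # every 12-residue arrangement with 6 hydrophobic residues
  pos <- utils::combn(12, 6)
  psis <- apply(pos, 2, function(ix) {
    e <- rep(-1L, 12)
    e[ix] <- 1L
    clustering_index(e)$psi
  })
  expect_equal(mean(psis), 1, tolerance = 1e-9)
  # also for an unbalanced composition and L = 2 blocks
  pos <- utils::combn(12, 3)
  psis <- apply(pos, 2, function(ix) {
    e <- rep(-1L, 12)
    e[ix] <- 1L
    clustering_index(e)$psi
  })
  expect_equal(mean(psis), 1, tolerance = 1e-9)
})

test_that("psi is invariant under reversal and encoding-preserving relabeling", {
  set.seed(42)
  for (i in 1:20) {
    L <- 6 * sample(3:8, 1)
    seqv <- sample(c("L", "I", "V", "A", "S", "T"), L, replace = TRUE)
    s1 <- paste(seqv, collapse = "")
    s2 <- paste(rev(seqv), collapse = "")
    s3 <- paste(chartr("LV", "VL", seqv), collapse = "")
    p1 <- clustering_index(s1)$psi
    expect_equal(clustering_index(s2)$psi, p1)
    expect_equal(clustering_index(s3)$psi, p1)
    if (!is.na(p1)) expect_gte(p1, 0)
  }
})

test_that("composition counts standard residues and excludes ambiguity codes", {
  expect_equal(composition("AAAA")$fractions[["A"]], 1.0)
  expect_equal(sum(composition("AAAA")$fractions), 1.0)
  cf <- composition("ACDE")$fractions
  expect_equal(unname(cf[c("A", "C", "D", "E")]), rep(0.25, 4))
  # B excluded from numerator and denominator
  cb <- composition("ACDEB")
  expect_equal(cb$length_used, 4L)
  expect_equal(unname(cb$fractions[c("A", "C", "D", "E")]), rep(0.25, 4))
  degenerate <- composition("XXBB")
  expect_equal(degenerate$length_used, 0L)
  expect_true(all(is.na(degenerate$fractions)))
})

test_that("composition fractions sum to one for random sequences", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    s <- paste(sample(aa, sample(10:200, 1), replace = TRUE), collapse = "")
    expect_equal(sum(composition(s)$fractions), 1, tolerance = 1e-9)
  }
})

test_that("mean disorder averages scores over optional ranges", {
  expect_equal(mean_disorder(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(mean_disorder(c(0.0, 1.0), range = c(2, 2)), 1.0)
  expect_equal(mean_disorder(rep(0.37, 10), range = c(3, 7)), 0.37)
  expect_error(mean_disorder(c(0.1, 0.2), range = c(2, 1)), "range")
  expect_error(mean_disorder(c(0.1, 0.2), range = c(1, 3)), "range")
})

test_that("mean disorder of a concatenation is the length-weighted mean", {
  set.seed(11)
  a <- runif(13)
  b <- runif(29)
  expect_equal(mean_disorder(c(a, b)),
               (13 * mean(a) + 29 * mean(b)) / 42)
})

test_that("cysteine excision removes C, preserves order, flags empties", {
  expect_equal(as.character(excise_cysteine("CACAC")), "AA")
  expect_equal(as.character(excise_cysteine("LIVF")), "LIVF")
  out <- excise_cysteine("CCC")
  expect_equal(as.character(out), "")
  expect_true(attr(out, "empty"))
  expect_equal(composition(excise_cysteine("CACAD"))$fractions[["C"]], 0)
})

test_that("surrogate disorder is a centered moving average of propensities", {
  tab <- default_disorder_propensity()
  # homopolymer: constant profile at the residue propensity
  hp <- surrogate_disorder(strrep("S", 30), window = 7)
  expect_equal(hp$scores, rep(tab[["S"]], 30))
  expect_identical(hp$source, "surrogate")
  # window 1 returns raw propensities
  raw <- surrogate_disorder("SLSL", window = 1)
  expect_equal(raw$scores, unname(tab[c("S", "L", "S", "L")]))
  # alternating 0/1 propensities, window 3: interior 1/3 or 2/3
  tab01 <- setNames(c(0, 1), c("L", "S"))
  alt <- surrogate_disorder("LSLSLS", propensity_table = tab01, window = 3)
  expect_equal(alt$scores[3], 2 / 3)
  expect_equal(alt$scores[4], 1 / 3)
  # truncated edge windows average over available residues
  expect_equal(alt$scores[1], 1 / 2)
  expect_error(surrogate_disorder("LS", window = 4), "odd")
})

test_that("instance metrics table matches scalar primitives row by row", {
  proteins <- tibble::tibble(
    species_id = "s1", gene_id = "g1",
    sequence = "AAAAALLLLLLAAAAAALLLLLLCCCDDD")
  annotations <- tibble::tibble(
    species_id = "s1", gene_id = "g1", pfam_id = c("PF1", "GENE"),
    start = c(6L, 1L), end = c(23L, 29L))
  m <- instance_metrics(proteins, annotations)
  sub <- substr(proteins$sequence, 6, 23)
  expect_equal(m$psi[1], clustering_index(sub)$psi)
  expect_equal(m$length, c(18L, 29L))
  scores <- surrogate_disorder(proteins$sequence)$scores
  expect_equal(m$mean_isd[1], mean(scores[6:23]))
  expect_equal(m$A[2], composition(proteins$sequence)$fractions[["A"]])
  expect_error(
    instance_metrics(proteins,
                     tibble::tibble(species_id = "s1", gene_id = "g1",
                                    pfam_id = "PF2", start = 5L, end = 99L)),
    "outside gene")
})
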