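#' Hydrophobicity encoding of a protein sequence
#'
#' Scores each residue as +1 (hydrophobic) or -1 (hydrophilic). The six most
#' hydrophobic amino acids Leu, Ile, Val, Phe, Met and Trp score +1; the
#' remaining standard amino acids score -1. Ambiguity and non-standard codes
#' are interpreted by the residues they stand for: B (Asp/Asn) -1,
#' J (Ile/Leu) +1, Z (Glu/Gln) -1, U (selenocysteine) -1, O (pyrrolysine) -1,
#' and X (unknown) conservatively -1.
#'
#' @param sequence A single amino-acid string (one-letter codes).
#' @return Integer vector of +1/-1 scores, one per residue, named by residue.
#' @examples
#' hydrophobicity_encode("LIVFMW")
#' hydrophobicity_encode("ACDE")
#' @export
hydrophobicity_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) {
    abort("`sequence` must be non-empty.")
  }
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  scores <- hydro_score_table()[res]
  if (anyNA(scores)) {
    bad <- which(is.na(scores))[1]
    abort(sprintf("Unknown residue '%s' at position %d.", res[bad], bad))
  }
  setNames(as.integer(scores), res)
}

hydro_score_table <- function() {
  tab <- setNames(rep(-1L, 20L), AA_STANDARD)
  tab[AA_HYDROPHOBIC] <- 1L
  c(tab, B = -1L, J = 1L, Z = -1L, U = -1L, O = -1L, X = -1L)
}

#' Normalized hydrophobic-clustering index (psi)
#'
#' Compares the variance of the +1/-1 hydrophobicity among blocks of
#' `block_size` consecutive residues to its expectation under a random
#' arrangement of the same composition, yielding a normalized index of
#' dispersion. A value of 1 indicates randomly interspersed hydrophobic
#' residues, values above 1 clustering, values below 1 over-dispersion.
#'
#' When the length L is not a multiple of `block_size` s, the index is
#' averaged over p = L mod s reading frames (starting offsets 0..p-1, the
#' tail truncated to N = s * floor(L/s) residues); when L is a multiple of s
#' a single frame is used. For each frame, block sums `sigma_k` total to
#' `M_f`, and
#' \deqn{\psi_f = \frac{s}{N} \sum_k \frac{(\sigma_k - s M_f/N)^2}{K}, \quad
#'       K = \frac{s (N^2 - M_f^2)}{N^2 - N}\left(1 - \frac{s}{N}\right)}
#' The reported psi is the mean over frames.
#'
#' The index is undefined (`defined = FALSE`, `psi = NA`) for sequences
#' shorter than two blocks, or when a frame contains residues of only one
#' sign (K = 0).
#'
#' @param sequence Amino-acid string, or an encoding from
#'   [hydrophobicity_encode()].
#' @param block_size Residues per block; default 6.
#' @return A list of class `clustering_index` with elements `psi`, `defined`,
#'   `reason`, `per_frame_psi`, `per_frame_totals`, `per_frame_normalizers`,
#'   `n_frames`, `block_size`, `truncated_length`, `length`.
#' @examples
#' clustering_index("LLLLLLAAAAAA")$psi  # 11
#' clustering_index("LLLAAALLLAAA")$psi  # 0
#' @export
clustering_index <- function(sequence, block_size = 6L) {
  s <- as.integer(block_size)
  stopifnot(s >= 2L)
  e <- if (is.character(sequence)) hydrophobicity_encode(sequence) else as.integer(sequence)
  L <- length(e)
  out <- list(psi = NA_real_, defined = FALSE, reason = NA_character_,
              per_frame_psi = numeric(0), per_frame_totals = numeric(0),
              per_frame_normalizers = numeric(0), n_frames = 0L,
              block_size = s, truncated_length = NA_integer_, length = L)
  class(out) <- "clustering_index"
  if (L < 2L * s) {
    out$reason <- "too short"
    return(out)
  }
  p <- max(1L, L %% s)
  N <- s * (L %/% s)
  out$n_frames <- p
  out$truncated_length <- N
  psi_f <- M_f <- K_f <- numeric(p)
  for (f in seq_len(p)) {
    x <- e[f:(f + N - 1L)]
    sigma <- colSums(matrix(x, nrow = s))
    M <- sum(sigma)
    M_f[f] <- M
    if (abs(M) == N) {
      out$per_frame_totals <- M_f
      out$reason <- "single-sign frame"
      return(out)
    }
    K <- s * (N^2 - M^2) / (N^2 - N) * (1 - s / N)
    K_f[f] <- K
    psi_f[f] <- (s / N) * sum((sigma - s * M / N)^2) / K
  }
  out$psi <- mean(psi_f)
  out$defined <- TRUE
  out$per_frame_psi <- psi_f
  out$per_frame_totals <- M_f
  out$per_frame_normalizers <- K_f
  out
}

#' @export
print.clustering_index <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<clustering_index> psi = %.4f (L = %d, %d frame%s of block size %d)\n",
                x$psi, x$length, x$n_frames, if (x$n_frames > 1) "s" else "", x$block_size))
  } else {
    cat(sprintf("<clustering_index> undefined (%s)\n", x$reason))
  }
  invisible(x)
}

# scalar psi; NA when undefined
psi_value <- function(sequence, block_size = 6L) {
  clustering_index(sequence, block_size)$psi
}

#' Amino-acid composition of a sequence
#'
#' Fraction of each of the 20 standard amino acids, counting occurrences and
#' dividing by the number of standard residues. Non-standard letters
#' (B, J, Z, U, O, X) are excluded from both numerator and denominator.
#'
#' @param sequence Amino-acid string.
#' @return A list with `fractions` (named 20-vector summing to 1) and
#'   `length_used`; `fractions` is all-`NA` when no standard residue remains.
#' @examples
#' composition("ACDE")$fractions[c("A", "C", "D", "E")]
#' @export
composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) abort("`sequence` must be non-empty.")
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(res, AA_STANDARD)
  idx <- idx[!is.na(idx)]
  n <- length(idx)
  if (n == 0L) {
    return(list(fractions = setNames(rep(NA_real_, 20L), AA_STANDARD), length_used = 0L))
  }
  counts <- tabulate(idx, nbins = 20L)
  list(fractions = setNames(counts / n, AA_STANDARD), length_used = n)
}

#' Mean intrinsic-disorder score
#'
#' Arithmetic mean of per-residue disorder scores, optionally over a 1-based
#' inclusive residue range (e.g. a pfam's interval within its gene).
#'
#' @param scores Numeric vector of per-residue scores in \[0, 1\].
#' @param range Optional `c(start, end)`, 1-based inclusive.
#' @return Scalar mean score.
#' @export
mean_disorder <- function(scores, range = NULL) {
  stopifnot(is.numeric(scores))
  if (!is.null(range)) {
    stopifnot(length(range) == 2L)
    if (range[1] < 1L || range[2] > length(scores) || range[1] > range[2]) {
      abort("`range` must be a non-empty 1-based interval within the profile.")
    }
    scores <- scores[range[1]:range[2]]
  }
  if (length(scores) == 0L) abort("Empty score range.")
  mean(scores)
}

#' Remove cysteine residues from a sequence
#'
#' Disorder predictors trained on structures score cysteines (mostly seen in
#' stable disulfide bonds) as strongly order-promoting; recomputing disorder
#' after excising cysteines checks whether that drives a trend.
#'
#' @param sequence Amino-acid string.
#' @return String with all `C` removed (possibly empty), with attribute
#'   `empty` set to `TRUE` when nothing remains.
#' @examples
#' excise_cysteine("CACAC")  # "AA"
#' @export
excise_cysteine <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  out <- gsub("C", "", toupper(sequence), fixed = TRUE)
  attr(out, "empty") <- nchar(out) == 0L
  out
}

#' Default per-residue disorder propensity table
#'
#' A simple monotone-in-hydrophilicity propensity: hydrophilic residues
#' (score -1 in the +1/-1 encoding) get `hi`, hydrophobic residues get `lo`.
#' Used by [surrogate_disorder()] and by the synthetic-data generator, so
#' that mean disorder tracks hydrophilic content.
#'
#' @param lo,hi Propensities for hydrophobic / hydrophilic residues.
#' @return Named numeric vector over the 26 supported residue codes.
#' @export
default_disorder_propensity <- function(lo = 0.05, hi = 0.90) {
  tab <- hydro_score_table()
  setNames(ifelse(tab > 0, lo, hi), names(tab))
}

#' Surrogate per-residue disorder profile
#'
#' A lightweight stand-in for an external disorder predictor: each residue's
#' score is the centered moving average (window `window`, odd) of per-residue
#' propensity values, with edge windows averaged over the available residues.
#' Real analyses can instead supply an external predictor's per-residue
#' scores; this surrogate keeps the pipeline self-contained and testable.
#'
#' @param sequence Amino-acid string.
#' @param propensity_table Named per-residue propensities in \[0, 1\];
#'   defaults to [default_disorder_propensity()].
#' @param window Odd window width >= 1.
#' @return A list with `scores` (numeric, one per residue) and
#'   `source = "surrogate"`.
#' @export
surrogate_disorder <- function(sequence,
                               propensity_table = default_disorder_propensity(),
                               window = 11L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("`window` must be an odd integer >= 1.")
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  prop <- propensity_table[res]
  if (anyNA(prop)) {
    bad <- which(is.na(prop))[1]
    abort(sprintf("No propensity for residue '%s' at position %d.", res[bad], bad))
  }
  prop <- as.numeric(prop)
  list(scores = running_mean(prop, window), source = "surrogate")
}

# centered moving average with truncated edge windows
running_mean <- function(x, window) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-instance sequence metrics table
#'
#' Computes, for each annotated domain instance (and optionally each whole
#' gene), the clustering index psi, mean disorder with and without cysteines,
#' interval length, and the 20 amino-acid fractions.
#'
#' @param proteins Tibble with `species_id`, `gene_id`, `sequence`.
#' @param annotations Tibble with `species_id`, `gene_id`, `pfam_id`,
#'   `start`, `end` (1-based inclusive). Pass rows with `pfam_id = "GENE"`
#'   and the full interval to score whole genes.
#' @param disorder Optional tibble `species_id`, `gene_id`, `scores`
#'   (list-column of per-residue numeric vectors covering the whole gene).
#'   When absent, scores come from [surrogate_disorder()].
#' @param block_size Block size for the clustering index.
#' @param disorder_window Window for the surrogate (also used to rescore
#'   cysteine-excised sequences).
#' @return Tibble: one row per annotation row, with columns `species_id`,
#'   `gene_id`, `pfam_id`, `start`, `end`, `length`, `psi`, `psi_defined`,
#'   `mean_isd`, `mean_isd_noC`, and the 20 single-letter composition columns.
#' @export
instance_metrics <- function(proteins, annotations, disorder = NULL,
                             block_size = 6L, disorder_window = 11L) {
  stopifnot(all(c("species_id", "gene_id", "sequence") %in% names(proteins)),
            all(c("species_id", "gene_id", "pfam_id", "start", "end") %in% names(annotations)))
  dat <- annotations %>%
    inner_join(proteins, by = c("species_id", "gene_id"))
  if (nrow(dat) < nrow(annotations)) {
    abort("Some annotations reference genes absent from `proteins`.")
  }
  if (!is.null(disorder)) {
    dat <- left_join(dat, disorder, by = c("species_id", "gene_id"))
  }
  prop <- default_disorder_propensity()
  hydro_tab <- hydro_score_table()
  n <- nrow(dat)
  has_scores <- "scores" %in% names(dat)
  psi <- isd <- isd_noc <- rep(NA_real_, n)
  psi_def <- logical(n)
  comp <- matrix(NA_real_, n, 20L, dimnames = list(NULL, AA_STANDARD))
  for (i in seq_len(n)) {
    start <- dat$start[i]; end <- dat$end[i]
    sequence <- dat$sequence[i]
    L <- nchar(sequence)
    if (start < 1L || end > L || start > end) {
      abort(sprintf("Interval [%d,%d] outside gene %s|%s (length %d).",
                    start, end, dat$species_id[i], dat$gene_id[i], L))
    }
    scores <- if (has_scores) dat$scores[[i]] else NULL
    if (is.null(scores)) {
      scores <- surrogate_disorder(sequence, prop, disorder_window)$scores
    }
    if (length(scores) != L) {
      abort(sprintf("Disorder profile length %d != gene length %d for %s|%s.",
                    length(scores), L, dat$species_id[i], dat$gene_id[i]))
    }
    isd[i] <- mean(scores[start:end])
    res <- strsplit(substr(sequence, start, end), "", fixed = TRUE)[[1]]
    enc <- unname(hydro_tab[res])
    if (anyNA(enc)) {
      bad <- which(is.na(enc))[1]
      abort(sprintf("Unknown residue '%s' at position %d of %s|%s.",
                    res[bad], start + bad - 1L, dat$species_id[i],
                    dat$gene_id[i]))
    }
    res_noc <- res[res != "C"]
    if (length(res_noc) > 0L) {
      isd_noc[i] <- mean(running_mean(as.numeric(prop[res_noc]),
                                      disorder_window))
    }
    ci <- clustering_index(enc, block_size)
    psi[i] <- ci$psi
    psi_def[i] <- ci$defined
    idx <- match(res, AA_STANDARD)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0L) comp[i, ] <- tabulate(idx, 20L) / length(idx)
  }
  out <- dat %>%
    select("species_id", "gene_id", "pfam_id", "start", "end") %>%
    mutate(length = .data$end - .data$start + 1L, psi = psi,
           psi_defined = psi_def, mean_isd = isd, mean_isd_noC = isd_noc)
  bind_cols(out, as_tibble(comp))
}
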