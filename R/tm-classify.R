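#' Transmembrane status of a gene
#'
#' A gene is transmembrane when the union of its predicted transmembrane
#' helix intervals covers strictly more than 18 residues. Overlapping helix
#' predictions are merged before counting.
#'
#' @param helices Tibble (or data frame) with `helix_start`, `helix_end`
#'   (1-based inclusive); zero rows means no predicted helix.
#' @param gene_length Optional gene length used to validate intervals.
#' @param threshold Residue-count threshold; coverage must exceed it.
#' @return Logical scalar.
#' @examples
#' gene_tm_status(tibble::tibble(helix_start = 1, helix_end = 19))   # TRUE
#' gene_tm_status(tibble::tibble(helix_start = 1, helix_end = 18))   # FALSE
#' @export
gene_tm_status <- function(helices, gene_length = NULL, threshold = 18L) {
  iv <- validate_helices(helices, gene_length)
  merged <- merge_intervals(iv)
  covered <- if (nrow(merged) == 0L) 0L else sum(merged$end - merged$start + 1L)
  covered > threshold
}

#' Transmembrane status of a pfam instance
#'
#' A pfam instance is transmembrane when some single predicted helix either
#' overlaps at least 50% of the pfam's length, or has at least 50% of its own
#' length inside the pfam. The two clauses are evaluated per helix (not on
#' pooled overlap) with exact integer arithmetic at the 50% boundary.
#'
#' @param pfam_interval `c(start, end)`, 1-based inclusive.
#' @param helices As in [gene_tm_status()].
#' @param gene_length Optional, for validation.
#' @return Logical scalar.
#' @export
pfam_tm_status <- function(pfam_interval, helices, gene_length = NULL) {
  stopifnot(length(pfam_interval) == 2L, pfam_interval[1] <= pfam_interval[2])
  iv <- validate_helices(helices, gene_length)
  if (nrow(iv) == 0L) return(FALSE)
  p_len <- pfam_interval[2] - pfam_interval[1] + 1L
  ov <- pmax(0L, pmin(iv$end, pfam_interval[2]) - pmax(iv$start, pfam_interval[1]) + 1L)
  h_len <- iv$end - iv$start + 1L
  any(2L * ov >= p_len | 2L * ov >= h_len)
}

validate_helices <- function(helices, gene_length = NULL) {
  if (is.null(helices) || nrow(helices) == 0L) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  iv <- tibble(start = as.integer(helices$helix_start),
               end = as.integer(helices$helix_end))
  if (any(iv$start > iv$end) || any(iv$start < 1L)) {
    abort("Helix intervals must satisfy 1 <= start <= end.")
  }
  if (!is.null(gene_length) && any(iv$end > gene_length)) {
    abort(sprintf("Helix interval exceeds gene length %d.", gene_length))
  }
  iv
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- arrange(iv, .data$start, .data$end)
  out_start <- iv$start[1]
  out_end <- iv$end[1]
  starts <- ends <- integer(0)
  for (i in 2:nrow(iv)) {
    if (iv$start[i] <= out_end + 1L) {
      out_end <- max(out_end, iv$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- iv$start[i]; out_end <- iv$end[i]
    }
  }
  tibble(start = c(starts, out_start), end = c(ends, out_end))
}

#' Classify all genes and pfam instances from a helix table
#'
#' Transmembrane and cytosolic domains face very different selective
#' environments, so downstream trend analyses are always run separately on
#' the two partitions, never pooled.
#'
#' @param annotations Tibble `species_id`, `gene_id`, `pfam_id`, `start`, `end`.
#' @param helices Tibble `species_id`, `gene_id`, `helix_start`, `helix_end`.
#' @param gene_lengths Optional tibble `species_id`, `gene_id`, `length` for
#'   interval validation.
#' @return List of two tibbles: `instances` (annotation rows plus `tm`),
#'   `genes` (`species_id`, `gene_id`, `tm`).
#' @export
classify_tm <- function(annotations, helices, gene_lengths = NULL) {
  if (any(helices$helix_start > helices$helix_end) ||
      any(helices$helix_start < 1L)) {
    abort("Helix intervals must satisfy 1 <= start <= end.")
  }
  if (!is.null(gene_lengths)) {
    chk <- helices %>%
      left_join(gene_lengths, by = c("species_id", "gene_id"))
    bad <- which(!is.na(chk$length) & chk$helix_end > chk$length)
    if (length(bad) > 0L) {
      abort(sprintf("Helix interval exceeds gene length for gene %s|%s.",
                    chk$species_id[bad[1]], chk$gene_id[bad[1]]))
    }
  }
  # gene status: merged-interval coverage > 18 residues
  cov <- helices %>%
    group_by(.data$species_id, .data$gene_id) %>%
    summarise(covered = {
      s <- .data$helix_start
      e <- .data$helix_end
      m <- merge_intervals(tibble(start = s, end = e))
      sum(m$end - m$start + 1L)
    }, .groups = "drop")
  genes <- annotations %>%
    distinct(.data$species_id, .data$gene_id) %>%
    left_join(cov, by = c("species_id", "gene_id")) %>%
    mutate(tm = dplyr::coalesce(.data$covered, 0L) > 18L) %>%
    select("species_id", "gene_id", "tm")
  # instance status: per-helix 50% reciprocal-overlap clauses
  ann <- annotations %>% mutate(.row = row_number())
  hits <- ann %>%
    inner_join(helices, by = c("species_id", "gene_id"),
               relationship = "many-to-many")
  tm_rows <- integer(0)
  if (nrow(hits) > 0L) {
    ov <- pmax(0L, pmin(hits$end, hits$helix_end) -
                 pmax(hits$start, hits$helix_start) + 1L)
    p_len <- hits$end - hits$start + 1L
    h_len <- hits$helix_end - hits$helix_start + 1L
    tm_rows <- unique(hits$.row[2L * ov >= p_len | 2L * ov >= h_len])
  }
  inst <- annotations
  inst$tm <- seq_len(nrow(inst)) %in% tm_rows
  list(instances = inst, genes = genes)
}
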