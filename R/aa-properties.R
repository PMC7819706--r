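#' Synthetic per-amino-acid property table
#'
#' A self-contained stand-in for externally curated amino-acid property
#' data, for demonstrations and tests: `rsa_hydrophobicity` (1 - mean
#' relative solvent accessibility, higher = more buried/hydrophobic),
#' `changeability` (relative evolutionary exchangeability), `cost`
#' (approximate high-energy phosphate bonds per synthesis), `essential`
#' (whether animals cannot synthesize it), and `recruitment_rank` (a
#' plausible chronology of recruitment into the genetic code, 1 =
#' earliest). All columns are synthetic, order-of-magnitude realistic
#' values constructed in code, not measurements; analyses of real data
#' should supply their own `aa_properties` table.
#'
#' @return Tibble with 20 rows: `aa`, `rsa_hydrophobicity`,
#'   `changeability`, `recruitment_rank`, `cost`, `essential`.
#' @export
synthetic_aa_properties <- function() {
  order_recruited <- c("G", "A", "D", "V", "P", "S", "E", "L", "T", "R",
                       "I", "Q", "N", "H", "K", "C", "F", "Y", "M", "W")
  rsa_buried <- c(A = 0.74, C = 0.91, D = 0.38, E = 0.36, F = 0.88,
                  G = 0.64, H = 0.62, I = 0.88, K = 0.28, L = 0.85,
                  M = 0.85, N = 0.44, P = 0.36, Q = 0.37, R = 0.36,
                  S = 0.54, T = 0.58, V = 0.86, W = 0.85, Y = 0.76)
  cost <- c(A = 11.7, C = 24.7, D = 12.7, E = 15.3, F = 52.0, G = 11.7,
            H = 38.3, I = 32.3, K = 30.3, L = 27.3, M = 34.3, N = 14.7,
            P = 20.3, Q = 16.3, R = 27.3, S = 11.7, T = 18.7, V = 23.3,
            W = 74.3, Y = 50.0)
  changeability <- c(A = 0.77, C = 0.30, D = 0.66, E = 0.72, F = 0.42,
                     G = 0.49, H = 0.54, I = 0.77, K = 0.71, L = 0.60,
                     M = 0.70, N = 0.79, P = 0.53, Q = 0.76, R = 0.66,
                     S = 0.82, T = 0.78, V = 0.74, W = 0.18, Y = 0.42)
  essential <- c("F", "H", "I", "K", "L", "M", "T", "V", "W")
  tibble(aa = AA_STANDARD,
         rsa_hydrophobicity = unname(rsa_buried[AA_STANDARD]),
         changeability = unname(changeability[AA_STANDARD]),
         recruitment_rank = match(AA_STANDARD, order_recruited),
         cost = unname(cost[AA_STANDARD]),
         essential = AA_STANDARD %in% essential)
}

#' Synthetic recruitment-criteria ranking matrix
#'
#' Builds an m-criterion matrix of rankings of the 20 amino acids by
#' perturbing a base chronology with rank noise — the input shape expected
#' by [consensus_recruitment_order()]. Purely synthetic, for tests and
#' demonstrations.
#'
#' @param m Number of criteria (columns).
#' @param noise Standard deviation of the rank perturbation before
#'   re-ranking.
#' @param base Optional named base ranking (defaults to the
#'   [synthetic_aa_properties()] chronology).
#' @return 20 x m numeric matrix, rows named by amino acid, columns
#'   `criterion_01`...
#' @export
synthetic_recruitment_criteria <- function(m = 10L, noise = 3,
                                           base = NULL) {
  if (is.null(base)) {
    props <- synthetic_aa_properties()
    base <- setNames(props$recruitment_rank, props$aa)
  }
  base <- base[AA_STANDARD]
  mat <- vapply(seq_len(m), function(j) {
    rank(base + rnorm(20, 0, noise), ties.method = "average")
  }, numeric(20))
  rownames(mat) <- AA_STANDARD
  colnames(mat) <- sprintf("criterion_%02d", seq_len(m))
  mat
}
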