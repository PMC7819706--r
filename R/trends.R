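#' Phylostratigraphy slope: linear trend of a property with age
#'
#' Ordinary least squares of a per-datapoint property value on assigned age,
#' with age converted from MY to billions of years (BY) so the slope reads
#' as property units per BY. All datapoints (including outliers) enter the
#' fit; datapoints with a missing value are dropped with a recorded count.
#'
#' @param datapoints Tibble with an age column (MY) and the property column.
#' @param property Property column name (string).
#' @param subset Optional logical expression (tidy-eval) selecting rows,
#'   e.g. `lineage_tag == "recent_animal" & !tm`.
#' @param age_col Age column name, in MY.
#' @param label Optional subset label stored on the result.
#' @param scale Multiplier applied to the property (use 100 for composition
#'   fractions to get percentage points).
#' @return Object of class `phylo_slope` (or `NULL` with a message when
#'   fewer than 3 datapoints remain): the `lm` fit plus metadata; see
#'   [tidy.phylo_slope()] and [glance.phylo_slope()].
#' @export
phylostrat_slope <- function(datapoints, property, subset = NULL,
                             age_col = "age_my", label = "all", scale = 1) {
  subset <- enquo(subset)
  if (!quo_is_null(subset)) {
    datapoints <- filter(datapoints, !!subset)
  }
  d <- tibble(age_by = datapoints[[age_col]] / 1000,
              value = datapoints[[property]] * scale)
  n_missing <- sum(!complete.cases(d))
  d <- d[complete.cases(d), ]
  if (nrow(d) < 3L) {
    inform(sprintf("Fewer than 3 datapoints for '%s' [%s]; no slope fitted.",
                   property, label))
    return(NULL)
  }
  fit <- lm(value ~ age_by, data = d)
  structure(list(fit = fit, property = property, subset = label,
                 n = nrow(d), n_missing = n_missing, scale = scale),
            class = "phylo_slope")
}

#' @export
print.phylo_slope <- function(x, ...) {
  td <- tidy(x)
  cat(sprintf(
    "<phylo_slope> %s [%s]: slope = %.4g per BY (se %.3g), R2 = %.3g, p = %.3g, n = %d\n",
    x$property, x$subset, td$slope, td$se, td$r_squared, td$p_value, x$n))
  invisible(x)
}

#' Tidy a phylostratigraphy slope fit
#'
#' @param x A `phylo_slope`.
#' @param conf_level Confidence level for the slope interval.
#' @param ... Unused.
#' @return One-row tibble: `property`, `subset`, `slope`, `se`, `r_squared`,
#'   `p_value`, `n`, `ci_low`, `ci_high` (slope in property units per BY).
#' @export
tidy.phylo_slope <- function(x, conf_level = 0.95, ...) {
  # summary.lm warns on numerically perfect fits; harmless here
  sm <- suppressWarnings(summary(x$fit))
  co <- sm$coefficients["age_by", ]
  ci <- suppressWarnings(stats::confint(x$fit, "age_by", level = conf_level))
  tibble(property = x$property, subset = x$subset,
         slope = unname(co["Estimate"]), se = unname(co["Std. Error"]),
         r_squared = sm$r.squared, p_value = unname(co["Pr(>|t|)"]),
         n = x$n, ci_low = ci[1], ci_high = ci[2])
}

#' @rdname tidy.phylo_slope
#' @return `glance()`: one-row model-level summary (`r_squared`, `sigma`,
#'   `p_value`, `n`, `n_missing`).
#' @export
glance.phylo_slope <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))
  tibble(r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         sigma = sm$sigma,
         p_value = unname(sm$coefficients["age_by", "Pr(>|t|)"]),
         n = x$n, n_missing = x$n_missing)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-amino-acid slope profile
#'
#' Fits one phylostratigraphy slope per amino-acid fraction (x 100, so
#' slopes are percentage points per BY) over a datapoint subset.
#'
#' @inheritParams phylostrat_slope
#' @return Tibble of class `aa_slope_profile`: `aa` (20 rows, alphabetical),
#'   `slope`, `se`, `p_value`, `n`, `subset`; amino acids whose fit fails
#'   carry `NA`.
#' @export
aa_slope_profile <- function(datapoints, subset = NULL, age_col = "age_my",
                             label = "all") {
  subset <- enquo(subset)
  if (!quo_is_null(subset)) {
    datapoints <- filter(datapoints, !!subset)
  }
  rows <- purrr::map(AA_STANDARD, function(aa) {
    if (!aa %in% names(datapoints)) {
      return(tibble(aa = aa, slope = NA_real_, se = NA_real_,
                    p_value = NA_real_, n = NA_integer_))
    }
    sl <- phylostrat_slope(datapoints, aa, age_col = age_col,
                           label = label, scale = 100)
    if (is.null(sl)) {
      return(tibble(aa = aa, slope = NA_real_, se = NA_real_,
                    p_value = NA_real_, n = NA_integer_))
    }
    td <- tidy(sl)
    tibble(aa = aa, slope = td$slope, se = td$se, p_value = td$p_value,
           n = td$n)
  })
  out <- bind_rows(rows)
  out$subset <- label
  class(out) <- c("aa_slope_profile", class(out))
  out
}

#' Correlation between two per-amino-acid profiles
#'
#' Rank (Spearman) or linear (Pearson) correlation of two 20-vectors (e.g.
#' two slope profiles, or a slope profile against a physico-chemical
#' property), with pairwise deletion of missing entries. Spearman p-values
#' use the t-approximation with average ranks for ties; for n > 3 a Fisher
#' z-transform standard error (sqrt(1.06/(n-3)) on the z scale) and its
#' back-transformed rho bounds are attached.
#'
#' @param x,y Numeric vectors of equal length (paired over amino acids).
#' @param method `"spearman"` or `"pearson"`.
#' @return One-row tibble: `method`, `rho`, `p_value`, `n`, `fisher_se`
#'   (z-scale; `NA` for Pearson or n <= 3), `rho_low`, `rho_high`.
#' @export
correlate_profiles <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) abort("Need at least two complete pairs.")
  if (n < 4L) {
    rho <- cor(x, y, method = method)
    return(tibble(method = method, rho = rho, p_value = NA_real_, n = n,
                  fisher_se = NA_real_, rho_low = NA_real_, rho_high = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  rho <- unname(ct$estimate)
  fse <- rho_low <- rho_high <- NA_real_
  if (method == "spearman" && n > 3L) {
    fse <- sqrt(1.06 / (n - 3))
    z <- atanh(rho)
    rho_low <- tanh(z - fse)
    rho_high <- tanh(z + fse)
  }
  tibble(method = method, rho = rho, p_value = ct$p.value, n = n,
         fisher_se = fse, rho_low = rho_low, rho_high = rho_high)
}

#' Consensus recruitment order of amino acids
#'
#' Mean rank across a matrix of ranking criteria (each column one criterion
#' ranking the 20 amino acids, ties allowed), optionally excluding criteria
#' — e.g. those based on protein composition itself, to avoid circularity.
#' No smoothing or filtering is applied after averaging.
#'
#' @param criteria_matrix Numeric matrix, 20 rows (named by amino acid) by
#'   m criteria columns.
#' @param excluded_criteria Column names or indices to exclude.
#' @return Named numeric vector of mean ranks (low = recruited early).
#' @export
consensus_recruitment_order <- function(criteria_matrix, excluded_criteria = NULL) {
  stopifnot(is.matrix(criteria_matrix), nrow(criteria_matrix) == 20L)
  keep <- seq_len(ncol(criteria_matrix))
  if (!is.null(excluded_criteria)) {
    drop_idx <- if (is.character(excluded_criteria)) {
      match(excluded_criteria, colnames(criteria_matrix))
    } else as.integer(excluded_criteria)
    if (anyNA(drop_idx)) abort("Unknown criterion in `excluded_criteria`.")
    keep <- setdiff(keep, drop_idx)
  }
  if (length(keep) == 0L) abort("All criteria excluded.")
  rowMeans(criteria_matrix[, keep, drop = FALSE])
}

#' Minimum-age sweep of a profile correlation
#'
#' For each age threshold, recomputes the per-amino-acid slope profile over
#' datapoints at least that old and correlates it with a fixed property
#' vector (e.g. the consensus recruitment order), tracking how the
#' correlation strengthens or decays as younger strata are excluded.
#'
#' @param datapoints Datapoint tibble with composition columns and `age_my`.
#' @param thresholds Numeric vector of minimum ages (MY).
#' @param property_vector Named 20-vector (names = amino acids).
#' @param method Correlation method.
#' @param subset Optional tidy-eval row filter applied before thresholding.
#' @return Tibble: one row per threshold with `min_age_my`, `n_datapoints`,
#'   and the [correlate_profiles()] columns (`NA` when a threshold leaves
#'   fewer than 3 datapoints or fewer than 4 defined slopes).
#' @export
min_age_sweep <- function(datapoints, thresholds, property_vector,
                          method = "spearman", subset = NULL) {
  subset <- enquo(subset)
  if (!quo_is_null(subset)) {
    datapoints <- filter(datapoints, !!subset)
  }
  stopifnot(!is.null(names(property_vector)))
  rows <- purrr::map(thresholds, function(th) {
    d <- filter(datapoints, .data$age_my >= th)
    base <- tibble(min_age_my = th, n_datapoints = nrow(d),
                   method = method, rho = NA_real_, p_value = NA_real_,
                   n = NA_integer_, fisher_se = NA_real_,
                   rho_low = NA_real_, rho_high = NA_real_)
    if (nrow(d) < 3L) return(base)
    prof <- aa_slope_profile(d, label = sprintf("age>=%g", th))
    m <- inner_join(as_tibble(prof)[, c("aa", "slope")],
                    tibble(aa = names(property_vector), prop = unname(property_vector)),
                    by = "aa")
    if (sum(complete.cases(m$slope, m$prop)) < 4L) return(base)
    cr <- correlate_profiles(m$slope, m$prop, method = method)
    bind_cols(tibble(min_age_my = th, n_datapoints = nrow(d)), cr)
  })
  bind_rows(rows)
}

#' Two-group and sign comparisons
#'
#' Welch's unequal-variance t-test (unpaired), the Wilcoxon signed-rank test
#' (paired; `a` and `b` aligned by `keys`), or a one-tailed binomial sign
#' test of whether positives exceed a 50% chance.
#'
#' @param a,b Numeric vectors. For `"binomial"`, `a` holds the values whose
#'   signs are tested and `b` is ignored.
#' @param type `"welch"`, `"wilcoxon"`, or `"binomial"`.
#' @param keys_a,keys_b Optional identifiers enforcing pairing for the
#'   Wilcoxon test; mismatched keys are an error.
#' @param alternative Alternative for the binomial test (default: more than
#'   half positive).
#' @return One-row tibble: `type`, `statistic`, `p_value`, `n_a`, `n_b`,
#'   `estimate`.
#' @export
group_comparisons <- function(a, b = NULL,
                              type = c("welch", "wilcoxon", "binomial"),
                              keys_a = NULL, keys_b = NULL,
                              alternative = "greater") {
  type <- match.arg(type)
  if (type == "welch") {
    ht <- t.test(a, b, var.equal = FALSE)
    return(tibble(type = type, statistic = unname(ht$statistic),
                  p_value = ht$p.value, n_a = length(a), n_b = length(b),
                  estimate = unname(diff(rev(ht$estimate)))))
  }
  if (type == "wilcoxon") {
    if (!is.null(keys_a) || !is.null(keys_b)) {
      if (is.null(keys_a) || is.null(keys_b) ||
          length(keys_a) != length(a) || length(keys_b) != length(b) ||
          !identical(sort(keys_a), sort(keys_b))) {
        abort("Paired comparison requires matching keys for `a` and `b`.")
      }
      b <- b[match(keys_a, keys_b)]
    } else if (length(a) != length(b)) {
      abort("Paired comparison requires equal-length vectors.")
    }
    diffs <- a - b
    if (all(diffs == 0)) {
      return(tibble(type = type, statistic = NA_real_, p_value = 1,
                    n_a = length(a), n_b = length(b), estimate = 0))
    }
    ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    return(tibble(type = type, statistic = unname(ht$statistic),
                  p_value = ht$p.value, n_a = length(a), n_b = length(b),
                  estimate = median(diffs)))
  }
  k <- sum(a > 0)
  n <- sum(a != 0)
  ht <- binom.test(k, n, p = 0.5, alternative = alternative)
  tibble(type = type, statistic = k, p_value = ht$p.value,
         n_a = n, n_b = NA_integer_, estimate = k / n)
}

#' Optional value transforms for trend analyses
#'
#' Raw (untransformed) values are the default throughout — slopes then keep
#' interpretable units — but a Box-Cox transform (lambda by profile maximum
#' likelihood) or the arcsine-square-root transform for proportions can be
#' applied for normality checks.
#'
#' @param values Numeric vector. Box-Cox requires positive values (a shift
#'   is applied and recorded if any value is <= 0); arcsine requires
#'   \[0, 1\].
#' @param kind `"boxcox"` or `"arcsine"`.
#' @param lambda Optional fixed Box-Cox lambda; when `NULL` (default) lambda
#'   is chosen by maximum likelihood.
#' @return List `transformed`, `kind`, `lambda` (Box-Cox), `shift`.
#' @export
transform_values <- function(values, kind = c("boxcox", "arcsine"),
                             lambda = NULL) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  if (kind == "arcsine") {
    if (any(values < 0 | values > 1)) {
      abort("Arcsine transform requires values in [0, 1].")
    }
    return(list(transformed = asin(sqrt(values)), kind = kind,
                lambda = NA_real_, shift = 0))
  }
  shift <- 0
  if (any(values <= 0)) {
    shift <- -min(values) + 1e-6 * diff(range(values)) + .Machine$double.eps
    values <- values + shift
  }
  if (is.null(lambda)) {
    bc <- MASS::boxcox(values ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
    lambda <- bc$x[which.max(bc$y)]
  }
  transformed <- if (abs(lambda) < 1e-8) log(values) else (values^lambda - 1) / lambda
  list(transformed = transformed, kind = kind, lambda = lambda, shift = shift)
}
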