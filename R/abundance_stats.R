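#' Per-sample cas-gene percentage
#'
#' `100 * n_cas_genes / n_total_genes` for each row of a sample inventory.
#'
#' @param inventory Data frame with `n_cas_genes` and `n_total_genes`.
#' @return Numeric vector of percentages.
#' @export
cas_percentage <- function(inventory) {
  if (any(inventory$n_total_genes <= 0)) stop("n_total_genes must be positive")
  if (any(inventory$n_cas_genes < 0 | inventory$n_cas_genes > inventory$n_total_genes)) {
    stop("n_cas_genes must lie in [0, n_total_genes]")
  }
  100 * inventory$n_cas_genes / inventory$n_total_genes
}

#' Two-tailed paired t-test
#'
#' Tests whether the mean paired difference is zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y`, sample SD, and a
#' two-tailed p-value from Student's t with `n - 1` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors paired by subject (n >= 2).
#' @return List with `t`, `p`, `df`, `mean_diff`, `n`, and `flag`
#'   (`"zero-variance"` when all differences are identical but non-zero,
#'   in which case `p` is reported as the 0 limit).
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0, n = n, flag = NA_character_))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1, mean_diff = mean(d),
                n = n, flag = "zero-variance"))
  }
  ht <- t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = unname(ht$estimate), n = n, flag = NA_character_)
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with non-zero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Compare cas-gene percentages between habitats
#'
#' Computes per-sample percentages, drops subjects missing any habitat
#' (listwise), and runs a two-tailed paired t-test for each requested
#' habitat pair.
#'
#' @param cohort Sample inventory data frame (`subject_id`, `habitat`,
#'   `n_total_genes`, `n_cas_genes`), e.g. from [simulate_cohort()].
#' @param pairs List of length-2 character vectors naming habitat pairs;
#'   default: all pairs present.
#' @return Data frame `habitat_a`, `habitat_b`, `n_pairs`, `mean_a`,
#'   `mean_b`, `mean_diff` (percentage points, a - b), `t_statistic`,
#'   `p_value`.
#' @export
compare_habitats <- function(cohort, pairs = NULL) {
  cohort$pct <- cas_percentage(cohort)
  wide <- tapply(cohort$pct, list(cohort$subject_id, cohort$habitat), mean)
  wide <- wide[complete.cases(wide), , drop = FALSE]
  habitats <- colnames(wide)
  if (is.null(pairs)) {
    pairs <- list()
    for (i in seq_len(length(habitats) - 1)) {
      for (j in seq(i + 1, length(habitats))) {
        pairs[[length(pairs) + 1L]] <- c(habitats[i], habitats[j])
      }
    }
  }
  rows <- lapply(pairs, function(p) {
    stopifnot(all(p %in% habitats))
    tt <- paired_ttest(wide[, p[1]], wide[, p[2]])
    data.frame(habitat_a = p[1], habitat_b = p[2], n_pairs = tt$n,
               mean_a = mean(wide[, p[1]]), mean_b = mean(wide[, p[2]]),
               mean_diff = tt$mean_diff, t_statistic = tt$t, p_value = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
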