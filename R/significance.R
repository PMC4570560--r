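## SILAC ratio computation and normalization, anchor chaining, the
## Significance A/B outlier statistics, BH adjustment, significant-set
## algebra and the volcano export.

#' Compute normalized log2 ratios for a named comparison
#'
#' For a direct comparison (both conditions measured in one set) the raw
#' ratio of a site is `log2(intensity_first / intensity_second)`. For a
#' cross-set comparison the ratio is chained through the anchor condition:
#' `log2(first / anchor)` in the first condition's set minus
#' `log2(second / anchor)` in the second condition's set, which with an
#' error-free anchor reduces to `log2(first / second)`. A site contributes
#' only if every required channel is present (chained comparisons need the
#' anchor channel in both sets).
#'
#' Ratios are median-centered per comparison (`center = TRUE`), so the
#' median log2 ratio is 0 after normalization; the subtracted offset is kept
#' in `attr(x, "centering_offset")`. The summed intensity is the sum of the
#' channels used; for chained ratios it is the minimum of the two legs'
#' summed intensities (the noisier leg limits the information content).
#'
#' @param sites a `phospho_sites` data.frame.
#' @param design a [silac_design()].
#' @param comparison name of a comparison defined in `design`.
#' @param center median-center the log2 ratios (default `TRUE`).
#' @return a `comparison_ratios` data.frame with columns `site_id`, `gene`,
#'   `residue`, `comparison`, `log2_ratio`, `summed_intensity`; positive
#'   ratios mean higher in the comparison's first condition.
#' @export
compute_ratios <- function(sites, design, comparison, center = TRUE) {
  stopifnot(inherits(design, "silac_design"))
  if (!comparison %in% names(design$comparisons)) {
    config_error(paste0("comparison '", comparison, "' not defined in design"))
  }
  conds <- design$comparisons[[comparison]]
  rows <- design$assignments

  direct_set <- NULL
  for (s in sort(unique(rows$set))) {
    in_s <- rows$condition[rows$set == s]
    if (all(conds %in% in_s)) {
      direct_set <- s
      break
    }
  }

  if (!is.null(direct_set)) {
    c1 <- design_slot(design, conds[1L], direct_set)
    c2 <- design_slot(design, conds[2L], direct_set)
    i1 <- sites[[intensity_col(c1$set[1L], c1$channel[1L])]]
    i2 <- sites[[intensity_col(c2$set[1L], c2$channel[1L])]]
    ok <- !is.na(i1) & !is.na(i2)
    log2r <- log2(i1[ok] / i2[ok])
    sumi <- i1[ok] + i2[ok]
    chained <- FALSE
  } else {
    s1 <- design_slot(design, conds[1L])
    s2 <- design_slot(design, conds[2L])
    if (!nrow(s1) || !nrow(s2)) {
      config_error(paste0("comparison '", comparison, "' has unassigned conditions"))
    }
    s1 <- s1[1L, ]
    s2 <- s2[1L, ]
    a1 <- design_slot(design, design$anchor, s1$set)[1L, ]
    a2 <- design_slot(design, design$anchor, s2$set)[1L, ]
    i1 <- sites[[intensity_col(s1$set, s1$channel)]]
    ia1 <- sites[[intensity_col(a1$set, a1$channel)]]
    i2 <- sites[[intensity_col(s2$set, s2$channel)]]
    ia2 <- sites[[intensity_col(a2$set, a2$channel)]]
    ok <- !is.na(i1) & !is.na(ia1) & !is.na(i2) & !is.na(ia2)
    log2r <- log2(i1[ok] / ia1[ok]) - log2(i2[ok] / ia2[ok])
    sumi <- pmin(i1[ok] + ia1[ok], i2[ok] + ia2[ok])
    chained <- TRUE
  }

  offset <- 0
  if (center && length(log2r)) {
    offset <- stats::median(log2r)
    log2r <- log2r - offset
  }
  out <- data.frame(
    site_id = sites$site_id[ok],
    gene = sites$gene[ok],
    residue = sites$residue[ok],
    comparison = if (sum(ok)) comparison else character(),
    log2_ratio = log2r,
    summed_intensity = sumi,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("comparison_ratios", "data.frame")
  attr(out, "comparison") <- comparison
  attr(out, "chained") <- chained
  attr(out, "centering_offset") <- offset
  out
}

#' Significance A: asymmetric outlier p-values for log ratios
#'
#' Scores each log ratio against the empirical spread of the whole ratio
#' distribution. With median `r0` and the 15.87/84.13 percentiles (the
#' `+/-1` sigma quantiles of a normal) estimated by linear interpolation
#' between order statistics, the side-specific scales are
#' `s+ = P84.13 - r0` and `s- = r0 - P15.87`, and each ratio gets
#' `z = (r - r0)/s+` above the median or `(r0 - r)/s-` below it. The
#' one-sided tail probability is `p = 1/2 * erfc(z / sqrt(2))`, i.e.
#' `1 - pnorm(z)`: `p = 0.5` at the median, `p ~ 0.1587` one scale unit out.
#'
#' Because each ratio is scored against its own side's tail only, a standard
#' normal null exceeds any threshold `alpha` at rate `2 * alpha`;
#' `two_sided = TRUE` doubles the tail probability (capped at 1), giving a
#' conventional calibrated two-sided p-value.
#'
#' @param log_ratios numeric vector of at least 3 finite log2 ratios.
#' @param two_sided double the one-sided tail probability (default `FALSE`,
#'   the classical definition).
#' @return numeric vector of p-values in `(0, 0.5]` (one-sided) or `(0, 1]`.
#' @export
significance_A <- function(log_ratios, two_sided = FALSE) {
  x <- log_ratios
  if (length(x) < 3L) statistic_error("significance_A needs >= 3 ratios")
  if (any(!is.finite(x))) statistic_error("non-finite log ratio")
  r0 <- stats::median(x)
  qs <- stats::quantile(x, probs = stats::pnorm(c(-1, 1)), type = 7L,
                        names = FALSE)
  s_minus <- r0 - qs[1L]
  s_plus <- qs[2L] - r0
  if (s_minus <= 0 || s_plus <= 0) {
    statistic_error(paste0(
      "degenerate percentile scale (s+ = ", signif(s_plus, 3L), ", s- = ",
      signif(s_minus, 3L), "); add jitter or provide a larger input"))
  }
  z <- ifelse(x > r0, (x - r0) / s_plus, (r0 - x) / s_minus)
  p <- stats::pnorm(z, lower.tail = FALSE)  # == erfc(z/sqrt(2)) / 2
  if (two_sided) p <- pmin(2 * p, 1)
  p
}

#' Significance B: Significance A within equal-occupancy intensity bins
#'
#' Ratio spread in SILAC data shrinks as summed peptide intensity grows, so a
#' global outlier test under-calls precise high-intensity sites. Significance
#' B orders sites by summed intensity, partitions them into contiguous
#' equal-occupancy bins of at least `min_bin` sites (the remainder is merged
#' into the last bin) and applies [significance_A()] within each bin, so
#' every site is judged against the ratio spread of comparably measured
#' peers. With fewer than `min_bin` sites a single bin is used (with a
#' warning) and the result equals Significance A exactly.
#'
#' @param log_ratios numeric vector of log2 ratios.
#' @param intensities summed intensities aligned with `log_ratios`.
#' @param min_bin minimum bin occupancy, default 300 (must be >= 3).
#' @param ids optional unique site ids used to break intensity ties
#'   deterministically in the binning order.
#' @inheritParams significance_A
#' @return p-values aligned to the input order.
#' @export
significance_B <- function(log_ratios, intensities, min_bin = 300L,
                           ids = NULL, two_sided = FALSE) {
  n <- length(log_ratios)
  if (length(intensities) != n) {
    value_error("log_ratios and intensities must be aligned")
  }
  if (min_bin < 3L) config_error("min_bin must be >= 3")
  if (is.null(ids)) ids <- seq_len(n)
  if (anyDuplicated(ids)) value_error("ids must be unique")
  if (n < min_bin) {
    warning("fewer sites (", n, ") than min_bin (", min_bin,
            "); Significance B reduces to Significance A")
    return(significance_A(log_ratios, two_sided = two_sided))
  }
  ord <- order(intensities, ids)
  n_bins <- max(1L, n %/% min_bin)
  sizes <- rep(min_bin, n_bins)
  sizes[n_bins] <- sizes[n_bins] + (n - min_bin * n_bins)
  bin_of <- rep.int(seq_len(n_bins), sizes)
  p <- numeric(n)
  for (b in seq_len(n_bins)) {
    idx <- ord[bin_of == b]
    p[idx] <- significance_A(log_ratios[idx], two_sided = two_sided)
  }
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; validates the
#' input range and preserves empty inputs.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return q-values, monotone non-decreasing in p-rank, all `<= 1`.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    value_error("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Attach outlier significance to a ratio table
#'
#' Computes Significance B (or A) p-values for a `comparison_ratios` table
#' and flags sites with `p < alpha`. Optionally attaches BH q-values; the
#' significance flag always uses the raw p-value, matching the analysis
#' convention of thresholding the outlier p-value directly at `alpha`.
#'
#' @param ratios a `comparison_ratios` data.frame from [compute_ratios()].
#' @param method `"B"` (intensity-binned, default) or `"A"` (global).
#' @param alpha significance threshold on the p-value, default 0.05.
#' @param adjust also compute BH q-values (default `FALSE`).
#' @inheritParams significance_B
#' @return the input with columns `p_value`, `significant` (and `q_value`).
#' @export
add_significance <- function(ratios, method = c("B", "A"), alpha = 0.05,
                             min_bin = 300L, two_sided = FALSE,
                             adjust = FALSE) {
  method <- match.arg(method)
  p <- if (method == "B") {
    significance_B(ratios$log2_ratio, ratios$summed_intensity,
                   min_bin = min_bin, ids = ratios$site_id,
                   two_sided = two_sided)
  } else {
    significance_A(ratios$log2_ratio, two_sided = two_sided)
  }
  ratios$p_value <- p
  if (adjust) ratios$q_value <- bh_adjust(p)
  ratios$significant <- p < alpha
  attr(ratios, "alpha") <- alpha
  attr(ratios, "method") <- method
  ratios
}

#' Extract the significant site set of a comparison
#'
#' @param ratios a `comparison_ratios` data.frame with a `p_value` column
#'   (see [add_significance()]).
#' @param alpha significance threshold, default 0.05.
#' @return data.frame keyed by `(gene, residue)` with columns `key`, `gene`,
#'   `residue`, `log2_ratio`, `p_value` and `direction`
#'   (`"higher_in_first"` / `"higher_in_second"`).
#' @export
significant_sites <- function(ratios, alpha = 0.05) {
  if (is.null(ratios$p_value)) {
    value_error("ratios lack p-values; run add_significance() first")
  }
  keep <- ratios$p_value < alpha
  out <- data.frame(
    key = site_key(ratios$gene[keep], ratios$residue[keep]),
    gene = ratios$gene[keep],
    residue = ratios$residue[keep],
    log2_ratio = ratios$log2_ratio[keep],
    p_value = ratios$p_value[keep],
    direction = ifelse(ratios$log2_ratio[keep] > 0,
                       "higher_in_first", "higher_in_second"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Cross-condition overlap of significant site sets
#'
#' Exact set algebra on `(gene, residue)` keys, with side-specific counts
#' split by ratio sign. Conservation: `|A| + |B| = only_a + only_b + 2*both`.
#'
#' @param set_a,set_b data.frames from [significant_sites()] (must have
#'   `key` and `log2_ratio` columns).
#' @return a `venn_counts` list: `n_a`, `n_b`, `only_a`, `only_b`, `both`,
#'   plus `a_up`, `a_down`, `b_up`, `b_down` (positive ratio = higher in the
#'   first condition of each comparison).
#' @export
venn_counts <- function(set_a, set_b) {
  ka <- unique(set_a$key)
  kb <- unique(set_b$key)
  both <- length(intersect(ka, kb))
  out <- list(
    n_a = length(ka), n_b = length(kb),
    only_a = length(ka) - both, only_b = length(kb) - both, both = both,
    a_up = sum(set_a$log2_ratio > 0), a_down = sum(set_a$log2_ratio < 0),
    b_up = sum(set_b$log2_ratio > 0), b_down = sum(set_b$log2_ratio < 0)
  )
  structure(out, class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("venn_counts: |A| = %d (%d up / %d down), |B| = %d (%d up / %d down)\n",
              x$n_a, x$a_up, x$a_down, x$n_b, x$b_up, x$b_down))
  cat(sprintf("  only A: %d, only B: %d, both: %d\n", x$only_a, x$only_b, x$both))
  invisible(x)
}

#' Volcano export rows
#'
#' @param ratios a `comparison_ratios` data.frame with `p_value` and
#'   `significant` columns.
#' @return data.frame with `gene`, `residue`, `comparison`, `log2_ratio`,
#'   `neg_log10_p` and `significant` (flag identical to
#'   [significant_sites()] membership at the same threshold).
#' @export
volcano_table <- function(ratios) {
  if (is.null(ratios$p_value)) {
    value_error("ratios lack p-values; run add_significance() first")
  }
  data.frame(
    gene = ratios$gene,
    residue = ratios$residue,
    comparison = ratios$comparison,
    log2_ratio = ratios$log2_ratio,
    neg_log10_p = -log10(ratios$p_value),
    significant = ratios$significant,
    stringsAsFactors = FALSE
  )
}
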