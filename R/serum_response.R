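## Serum-withdrawal response classification: partition sites by their
## log2(high serum / serum starvation) ratios in proficient (x) versus
## deficient (y) cells into correlated, persistent-in-deficient (blue),
## lost-in-deficient (gray) and unclassified groups.

SERUM_LABELS <- c("correlated", "persistent_in_deficient",
                  "lost_in_deficient", "unclassified")

#' Classify a site's serum-withdrawal response
#'
#' `x` is the site's log2(high serum / serum starvation) ratio in proficient
#' cells and `y` the same ratio in deficient cells. Sites regulated in a
#' coordinated manner in both genotypes are `correlated` (excluded from the
#' downstream network analysis): same sign, both magnitudes at least
#' `tau_null`, and `|x - y| < tau_change`. Anti-correlated sites are
#' `persistent_in_deficient` ("blue": `x >= tau_change`, `y <= tau_null` —
#' the site loses phosphorylation on starvation only in proficient cells,
#' i.e. stays phosphorylated in deficient cells) or `lost_in_deficient`
#' ("gray": the axis-swapped mirror). Everything else is `unclassified`.
#' Where the correlated band and an anti-correlated corner touch, the
#' correlated rule wins (exclusion precedes selection).
#'
#' @param x,y finite numeric vectors of equal length.
#' @param tau_change log2 threshold for a clear serum response, default 1.
#' @param tau_null log2 threshold below which a response counts as null,
#'   default 0.5; must satisfy `tau_change > tau_null >= 0`.
#' @return factor with levels `correlated`, `persistent_in_deficient`,
#'   `lost_in_deficient`, `unclassified`.
#' @export
#' @examples
#' classify_serum_response(c(2, 2, 0), c(2, 0, 2))
classify_serum_response <- function(x, y, tau_change = 1, tau_null = 0.5) {
  if (length(x) != length(y)) value_error("x and y must be aligned")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    value_error("non-finite serum-response ratio")
  }
  if (!(tau_change > tau_null && tau_null >= 0)) {
    config_error("need tau_change > tau_null >= 0")
  }
  correlated <- sign(x) == sign(y) & pmin(abs(x), abs(y)) >= tau_null &
    abs(x - y) < tau_change
  blue <- x >= tau_change & y <= tau_null
  gray <- y >= tau_change & x <= tau_null
  lab <- rep("unclassified", length(x))
  lab[gray] <- "lost_in_deficient"
  lab[blue] <- "persistent_in_deficient"
  lab[correlated] <- "correlated"
  factor(lab, levels = SERUM_LABELS)
}

#' Join serum-withdrawal ratios of the two genotypes
#'
#' Inner join on `(gene, residue)` of the proficient-cell comparison
#' (`x`) with the deficient-cell comparison (`y`); sites missing either
#' ratio are skipped (they are unquantified, not "unclassified").
#'
#' @param ratios_x `comparison_ratios` for high vs. low serum in proficient
#'   cells.
#' @param ratios_y same in deficient cells.
#' @return data.frame with `key`, `gene`, `residue`, `x`, `y`.
#' @export
serum_response_pairs <- function(ratios_x, ratios_y) {
  dx <- data.frame(key = site_key(ratios_x$gene, ratios_x$residue),
                   gene = ratios_x$gene, residue = ratios_x$residue,
                   x = ratios_x$log2_ratio, stringsAsFactors = FALSE)
  dy <- data.frame(key = site_key(ratios_y$gene, ratios_y$residue),
                   y = ratios_y$log2_ratio, stringsAsFactors = FALSE)
  out <- merge(dx, dy, by = "key", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Partition sites by serum-withdrawal response
#'
#' Applies [classify_serum_response()] to every joined `(x, y)` pair and
#' collapses site labels to deduplicated protein sets per label for the
#' network stage.
#'
#' @param pairs data.frame from [serum_response_pairs()] (columns `gene`,
#'   `residue`, `x`, `y`).
#' @inheritParams classify_serum_response
#' @return a `serum_partition` list: `table` (per-site classification),
#'   `proteins` (label -> unique gene symbols), `counts` (sites per label)
#'   and `n` (number of classified pairs).
#' @export
partition_sites <- function(pairs, tau_change = 1, tau_null = 0.5) {
  lab <- classify_serum_response(pairs$x, pairs$y,
                                 tau_change = tau_change, tau_null = tau_null)
  tab <- data.frame(gene = pairs$gene, residue = pairs$residue,
                    x = pairs$x, y = pairs$y, label = as.character(lab),
                    stringsAsFactors = FALSE)
  proteins <- lapply(stats::setNames(SERUM_LABELS, SERUM_LABELS), function(l) {
    sort(unique(tab$gene[tab$label == l]))
  })
  counts <- table(factor(tab$label, levels = SERUM_LABELS))
  structure(list(table = tab, proteins = proteins,
                 counts = as.integer(counts), labels = SERUM_LABELS,
                 n = nrow(tab)),
            class = "serum_partition")
}

#' @export
print.serum_partition <- function(x, ...) {
  cat("serum_partition over", x$n, "site pairs:\n")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %-24s %6d sites, %5d proteins\n", x$labels[i],
                x$counts[i], length(x$proteins[[x$labels[i]]])))
  }
  invisible(x)
}
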