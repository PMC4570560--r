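## Residue-level kinase-target-set enrichment on a pre-ranked site list:
## classic (unweighted, Kolmogorov-Smirnov) running-sum enrichment score,
## gene-set-permutation normalized enrichment score, permutation p-values
## and permutation FDR, with leading-edge extraction.

#' Build residue-level kinase target sets
#'
#' Groups species-filtered kinase-substrate records by kinase, keys members
#' by `(gene, residue)`, intersects each set with the ranked universe
#' (members absent from the universe are silently excluded — effective-size
#' semantics) and drops sets whose effective size falls below `min_size`.
#'
#' @param records data.frame from [read_kinase_substrates()].
#' @param universe character vector of ranked-universe site keys
#'   (see [site_key()]).
#' @param min_size minimum effective set size to score, default 3.
#' @return named list of member-key vectors; a `dropped` attribute records
#'   kinases removed for insufficient overlap.
#' @export
build_target_sets <- function(records, universe, min_size = 3L) {
  if (!length(universe)) config_error("empty ranked universe")
  universe <- unique(universe)
  keys <- site_key(records$substrate_gene, records$residue)
  sets <- lapply(split(keys, records$kinase), function(k) {
    sort(intersect(unique(k), universe))
  })
  small <- lengths(sets) < min_size
  out <- sets[!small]
  attr(out, "dropped") <- names(sets)[small]
  out
}

#' Rank quantified sites by their log2 ratio
#'
#' Produces the pre-ranked list for enrichment scoring. The default
#' orientation, `"deficient_first"`, places the most negative
#' log2(proficient/deficient) ratios — sites most phosphorylated in
#' deficient cells — at the top, so a kinase whose targets are
#' hyperphosphorylated in deficient cells receives a positive enrichment
#' score. Ties in the metric are broken deterministically by site key.
#'
#' @param ratios a `comparison_ratios` data.frame.
#' @param orientation `"deficient_first"` (ascending ratio, default) or
#'   `"proficient_first"` (descending).
#' @return a `ranked_sites` object: `keys`, `metric` (in ranked order) and
#'   `orientation`.
#' @export
rank_sites <- function(ratios, orientation = c("deficient_first",
                                               "proficient_first")) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(ratios$log2_ratio))) value_error("non-finite ranking metric")
  keys <- site_key(ratios$gene, ratios$residue)
  metric <- ratios$log2_ratio
  if (anyDuplicated(keys)) {
    # one ratio per (gene, residue): keep the best-measured occurrence
    o <- order(keys, -ratios$summed_intensity)
    keep <- !duplicated(keys[o])
    sel <- o[keep]
    warning(sum(!keep), " duplicate site key(s) collapsed by summed intensity")
    keys <- keys[sel]
    metric <- metric[sel]
  }
  ord <- if (orientation == "deficient_first") {
    order(metric, keys)
  } else {
    order(-metric, keys)
  }
  structure(list(keys = keys[ord], metric = metric[ord],
                 orientation = orientation),
            class = "ranked_sites")
}

#' @export
length.ranked_sites <- function(x) length(x$keys)

## ES from sorted hit positions only: the running sum rises by 1/k at each
## hit and falls by 1/(N-k) at each miss, so its local maxima sit right
## after hits and its local minima right before hits (plus the terminal 0).
## Computed in exact integer units of 1/(k*(N-k)) so that ties between the
## positive and negative extremes are decided exactly (toward positive).
es_from_hits <- function(pos, N, k) {
  j <- seq_len(k)
  miss_before <- (pos - j) * k
  after <- j * (N - k) - miss_before
  before <- (j - 1) * (N - k) - miss_before
  mp <- max(after, 0)
  mn <- min(before, 0)
  (if (mp >= -mn) mp else mn) / (k * (N - k))
}

#' Running-sum enrichment score of one target set
#'
#' Walks the ranked list accumulating `+1/k` at set members ("hits") and
#' `-1/(N-k)` at non-members; the enrichment score ES is the signed maximum
#' deviation of this running sum from zero (ties between equal positive and
#' negative deviations resolve to the positive side). With unit increments
#' this is the classic two-sample Kolmogorov-Smirnov statistic between the
#' hit positions and the uniform distribution on ranks. The leading edge is
#' the hits at or before the extremum for positive ES, and strictly after it
#' for negative ES.
#'
#' @param ranked a `ranked_sites` object.
#' @param members character vector of member keys.
#' @return list with `ES`, `running_sum` (length-N numeric), `leading_edge`
#'   (member keys in rank order) and `size` (effective set size).
#' @export
enrichment_score <- function(ranked, members) {
  stopifnot(inherits(ranked, "ranked_sites"))
  N <- length(ranked)
  hits <- ranked$keys %in% members
  k <- sum(hits)
  if (k == 0L || k == N) {
    statistic_error(paste0("degenerate set: ", k, " of ", N,
                           " ranked sites are members"))
  }
  ## exact integer running sum in units of 1/(k*(N-k)): ties between the
  ## positive and negative extremes resolve deterministically to positive
  unit <- k * (N - k)
  rs_int <- cumsum(ifelse(hits, N - k, -k))
  mp <- max(rs_int)
  mn <- min(rs_int)
  if (mp >= -mn) {
    es <- mp / unit
    ext <- which.max(rs_int)
    le <- ranked$keys[hits & seq_len(N) <= ext]
  } else {
    es <- mn / unit
    ext <- which.min(rs_int)
    le <- ranked$keys[hits & seq_len(N) > ext]
  }
  list(ES = es, running_sum = rs_int / unit, leading_edge = le, size = k)
}

#' Permutation-normalized enrichment scores
#'
#' Scores every target set against the ranked list and builds a null by
#' drawing, for each of `n_perm` permutations, a random member set of equal
#' effective size from the universe (gene-set permutation: a single
#' pre-ranked list offers no sample labels to permute). For each set,
#' `NES = ES / mean(|null ES| of matching sign)` and
#' `p_perm = (1 + #(|null ES| >= |ES|, matching sign)) / (1 + #matching-sign
#' nulls)`. Null ES values are normalized by the same per-set, per-sign
#' normalizer to form the null NES pool consumed by [gsea_fdr()].
#' Reproducible given `seed`.
#'
#' @param ranked a `ranked_sites` object.
#' @param sets named list of member-key vectors (see [build_target_sets()]).
#' @param n_perm number of permutations, at least 100; default 1000.
#' @param seed integer RNG seed (mandatory).
#' @return a `kinase_enrichment` object: `table` (kinase, size, ES, NES,
#'   p_perm, no_matching_null flag), `leading_edges`, `null_nes` (per-set
#'   normalized null scores), `n_perm`, `seed`.
#' @export
normalized_enrichment <- function(ranked, sets, n_perm = 1000L, seed) {
  stopifnot(inherits(ranked, "ranked_sites"))
  if (missing(seed) || is.null(seed)) config_error("a permutation seed is mandatory")
  if (n_perm < 100L) config_error("n_perm must be >= 100")
  if (!length(sets)) config_error("no target sets to score")
  N <- length(ranked)
  set.seed(as.integer(seed))

  rows <- vector("list", length(sets))
  ledges <- vector("list", length(sets))
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    obs <- enrichment_score(ranked, sets[[i]])
    k <- obs$size
    nulls <- vapply(seq_len(n_perm), function(.) {
      es_from_hits(sort.int(sample.int(N, k)), N, k)
    }, numeric(1L))
    mean_pos <- mean(nulls[nulls > 0])
    mean_neg <- mean(abs(nulls[nulls < 0]))
    same_sign <- if (obs$ES >= 0) nulls[nulls > 0] else nulls[nulls < 0]
    n_match <- length(same_sign)
    p_perm <- (1 + sum(abs(same_sign) >= abs(obs$ES))) / (1 + n_match)
    nes <- if (obs$ES >= 0) {
      if (is.finite(mean_pos) && mean_pos > 0) obs$ES / mean_pos else NA_real_
    } else {
      if (is.finite(mean_neg) && mean_neg > 0) obs$ES / mean_neg else NA_real_
    }
    null_nes[[i]] <- ifelse(nulls > 0, nulls / mean_pos, nulls / mean_neg)
    rows[[i]] <- data.frame(
      kinase = names(sets)[i], size = k, ES = obs$ES, NES = nes,
      p_perm = p_perm, no_matching_null = n_match == 0L,
      stringsAsFactors = FALSE
    )
    ledges[[i]] <- obs$leading_edge
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  names(ledges) <- tab$kinase
  names(null_nes) <- tab$kinase
  structure(list(table = tab, leading_edges = ledges, null_nes = null_nes,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "kinase_enrichment")
}

#' Permutation FDR for normalized enrichment scores
#'
#' For each observed NES, the FDR estimate is the fraction of pooled null
#' NES values at least as extreme (matching sign) divided by the fraction of
#' observed NES values at least as extreme (matching sign), clipped to
#' `[0, 1]` and then monotone-adjusted so FDR is non-increasing in `|NES|`.
#' With a single scored set there is no meaningful observed tail, so the
#' permutation p-value is used as a flagged fallback.
#'
#' @param res a `kinase_enrichment` object from [normalized_enrichment()].
#' @return the same object with `FDR` (and `fdr_method`) added to `table`.
#' @export
gsea_fdr <- function(res) {
  stopifnot(inherits(res, "kinase_enrichment"))
  tab <- res$table
  obs <- tab$NES
  if (nrow(tab) == 1L) {
    tab$FDR <- tab$p_perm
    tab$fdr_method <- "p_perm_fallback"
    res$table <- tab
    return(res)
  }
  pool <- unlist(res$null_nes, use.names = FALSE)
  pool <- pool[is.finite(pool)]
  pos_pool <- pool[pool > 0]
  neg_pool <- pool[pool < 0]
  pos_obs <- obs[!is.na(obs) & obs >= 0]
  neg_obs <- obs[!is.na(obs) & obs < 0]
  fdr <- vapply(obs, function(nes) {
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      fn <- if (length(pos_pool)) mean(pos_pool >= nes) else 0
      fo <- mean(pos_obs >= nes)
    } else {
      fn <- if (length(neg_pool)) mean(neg_pool <= nes) else 0
      fo <- mean(neg_obs <= nes)
    }
    min(1, max(0, fn / fo))
  }, numeric(1L))
  ## enforce monotonicity: larger |NES| never has larger FDR. Each set's
  ## FDR is raised to the worst among sets at least as extreme
  ## (conservative direction).
  ok <- which(!is.na(fdr))
  o <- ok[order(abs(obs[ok]))]
  fdr[o] <- rev(cummax(rev(fdr[o])))
  tab$FDR <- fdr
  tab$fdr_method <- "permutation"
  res$table <- tab
  res
}

#' One-call kinase target-set enrichment
#'
#' [normalized_enrichment()] followed by [gsea_fdr()], with the result table
#' ordered by decreasing NES.
#'
#' @inheritParams normalized_enrichment
#' @return a `kinase_enrichment` object with FDR, sorted by decreasing NES.
#' @export
kinase_enrichment <- function(ranked, sets, n_perm = 1000L, seed) {
  res <- gsea_fdr(normalized_enrichment(ranked, sets, n_perm = n_perm,
                                        seed = seed))
  o <- order(-res$table$NES, res$table$kinase)
  res$table <- res$table[o, , drop = FALSE]
  rownames(res$table) <- NULL
  res
}

#' @export
print.kinase_enrichment <- function(x, ...) {
  cat("kinase_enrichment:", nrow(x$table), "sets,", x$n_perm,
      "permutations (seed", paste0(x$seed, ")\n"))
  print(x$table, row.names = FALSE, digits = 3L)
  invisible(x)
}

#' Flatten an enrichment result for TSV export
#'
#' @param res a `kinase_enrichment` object.
#' @return data.frame with the result table plus a semicolon-joined
#'   `leading_edge` column.
#' @export
enrichment_report <- function(res) {
  stopifnot(inherits(res, "kinase_enrichment"))
  tab <- res$table
  tab$leading_edge <- vapply(tab$kinase, function(k) {
    paste(res$leading_edges[[k]], collapse = ";")
  }, character(1L))
  tab
}
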