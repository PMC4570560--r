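# Small in-code fixtures shared across test files.

# Minimal site table with explicit intensities; any unspecified channel is NA.
make_sites <- function(..., localization = 0.99) {
  rows <- list(...)
  cols <- c("site_id", "protein_id", "gene", "residue", "localization_prob",
            paste0("int_set", rep(1:2, each = 3), "_",
                   rep(c("light", "medium", "heavy"), 2)))
  df <- as.data.frame(stats::setNames(
    c(list(character(), character(), character(), character(), numeric()),
      rep(list(numeric()), 6)), cols))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    line <- as.list(rep(NA_real_, length(cols)))
    names(line) <- cols
    line$site_id <- r$site_id %||% sprintf("s%03d", i)
    line$protein_id <- r$protein_id %||% paste0("P", i)
    line$gene <- r$gene
    line$residue <- r$residue
    line$localization_prob <- r$localization_prob %||% localization
    for (nm in names(r)) if (nm %in% cols) line[[nm]] <- r[[nm]]
    df[i, ] <- line
  }
  class(df) <- c("phospho_sites", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ratio table wrapper for rank_sites / enrichment tests.
make_ratios <- function(metric, genes = sprintf("G%03d", seq_along(metric)),
                        residues = rep("S1", length(metric)),
                        intensity = seq_along(metric)) {
  r <- data.frame(site_id = sprintf("s%03d", seq_along(metric)),
                  gene = genes, residue = residues,
                  comparison = "cmp", log2_ratio = metric,
                  summed_intensity = intensity, stringsAsFactors = FALSE)
  class(r) <- c("comparison_ratios", "data.frame")
  r
}

# Independent brute-force enrichment score: walk the ranked list position by
# position, track the running sum and its signed maximum deviation. Counted
# in whole units of 1/(k*(N-k)) so the enumeration is exact and ties between
# the positive and negative extremes are decided without rounding.
brute_force_es <- function(is_hit) {
  N <- length(is_hit)
  k <- sum(is_hit)
  cs <- 0
  best_pos <- 0
  best_neg <- 0
  for (i in seq_len(N)) {
    cs <- cs + if (is_hit[i]) N - k else -k
    if (cs > best_pos) best_pos <- cs
    if (cs < best_neg) best_neg <- cs
  }
  (if (best_pos >= -best_neg) best_pos else best_neg) / (k * (N - k))
}

# A small deterministic synthetic configuration for fast tests.
quick_config <- function(seed, ...) {
  args <- list(seed = seed, n_proteins = 300, sites_per_protein = 2,
               kinase_n_decoy = 5, kinase_set_size = 15,
               module_count = 2, module_size = 6, annotation_n_terms = 10)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}
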