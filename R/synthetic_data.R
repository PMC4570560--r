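## Synthetic study generator with planted ground truth. Emulates the
## statistical structure the analysis assumes: log-normal channel
## intensities, intensity-dependent heteroscedastic log-ratio noise,
## planted differential phosphosites, planted serum-response classes,
## planted kinase-target shifts, and annotation/network modules.

#' Configuration of the synthetic study
#'
#' All randomness flows from `seed`; independent substreams drive the site
#' table, the kinase-substrate table and the annotation/network tables, so
#' regenerating one never perturbs the others.
#'
#' Channel noise is additive on the log2 scale with standard deviation
#' `sigma(I) = noise_floor + noise_amplitude * exp(-noise_decay * (I -
#' intensity_min))`, where `I` is the site's base log2 intensity: ratio
#' noise is the difference of two channel noises, so ratio spread shrinks
#' with intensity exactly as the binned outlier statistic assumes. Setting
#' `noise_amplitude = 0` gives a homoscedastic null.
#'
#' Planted structure:
#' * a fraction `pi_diff` of sites receives a genotype effect on the
#'   log2(proficient/deficient) ratio drawn as `sign * |N(effect_mean,
#'   effect_sd)|`;
#' * serum-response classes get true `(x, y)` serum-withdrawal responses of
#'   `(s, s)` (correlated), `(s, 0)` (persistent in deficient) or `(0, s)`
#'   (lost in deficient) with `s = serum_effect`; remaining sites are null;
#' * each planted kinase set shifts the genotype effect of its members by
#'   `kinase_delta` log2 units (decoy sets receive no shift);
#' * network modules are term-coherent and densely connected above 0.9.
#'
#' @param seed integer seed (mandatory).
#' @param n_proteins number of proteins.
#' @param sites_per_protein mean sites per protein (zero-truncated Poisson).
#' @param log2_intensity_mean,log2_intensity_sd base log2-intensity model.
#' @param noise_floor,noise_amplitude,noise_decay channel-noise model
#'   parameters (all `>= 0`, `noise_floor > 0`).
#' @param intensity_min reference intensity of the noise model; defaults to
#'   `log2_intensity_mean - 2 * log2_intensity_sd`.
#' @param pi_diff fraction of sites with a planted genotype effect.
#' @param effect_mean,effect_sd magnitude distribution of planted log2
#'   genotype effects.
#' @param serum_props named proportions for `correlated`,
#'   `persistent_in_deficient`, `lost_in_deficient` (must sum to `<= 1`).
#' @param serum_effect log2 magnitude of a clear serum response.
#' @param kinase_n_planted,kinase_n_decoy,kinase_set_size,kinase_delta
#'   kinase-target planting: number of shifted sets, number of unshifted
#'   decoy sets, members per set, log2 shift of planted members.
#' @param missing_rate per-channel missingness probability.
#' @param annotation_n_terms background annotation terms.
#' @param module_count,module_size network/annotation modules.
#' @param module_edge_prob probability an intra-module edge scores high.
#' @param module_score_range,background_score_range uniform score ranges.
#' @param background_edge_prob density of background edges.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             n_proteins = 1200L,
                             sites_per_protein = 2.5,
                             log2_intensity_mean = 25,
                             log2_intensity_sd = 2,
                             noise_floor = 0.15,
                             noise_amplitude = 0.6,
                             noise_decay = 0.4,
                             intensity_min = NULL,
                             pi_diff = 0.05,
                             effect_mean = 2,
                             effect_sd = 0.5,
                             serum_props = c(correlated = 0.15,
                                             persistent_in_deficient = 0.04,
                                             lost_in_deficient = 0.04),
                             serum_effect = 2,
                             kinase_n_planted = 1L,
                             kinase_n_decoy = 20L,
                             kinase_set_size = 30L,
                             kinase_delta = -2,
                             missing_rate = 0.03,
                             annotation_n_terms = 40L,
                             module_count = 3L,
                             module_size = 8L,
                             module_edge_prob = 0.9,
                             module_score_range = c(0.92, 0.99),
                             background_edge_prob = 0.01,
                             background_score_range = c(0.15, 0.85)) {
  if (missing(seed) || is.null(seed)) config_error("a seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (is.null(cfg$intensity_min)) {
    cfg$intensity_min <- log2_intensity_mean - 2 * log2_intensity_sd
  }
  if (noise_floor <= 0 || noise_amplitude < 0 || noise_decay < 0) {
    config_error("noise model requires noise_floor > 0 and amplitude, decay >= 0")
  }
  if (pi_diff < 0 || pi_diff > 1) config_error("pi_diff must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) {
    config_error("missing_rate must lie in [0, 1)")
  }
  want <- c("correlated", "persistent_in_deficient", "lost_in_deficient")
  if (!all(want %in% names(serum_props)) || any(serum_props < 0) ||
      sum(serum_props) > 1) {
    config_error("serum_props must name the three classes, be >= 0 and sum to <= 1")
  }
  structure(cfg, class = "synthetic_config")
}

noise_sd <- function(cfg, base_log2) {
  cfg$noise_floor + cfg$noise_amplitude *
    exp(-cfg$noise_decay * (base_log2 - cfg$intensity_min))
}

#' Generate a synthetic phosphosite table with planted truth
#'
#' Channel intensities are `2^(base + condition effect + noise)` with the
#' per-channel noise standard deviation given by the configured intensity-
#' dependent model; the anchor condition shares its true value across both
#' sets (with independent measurement noise). Missingness is applied last;
#' sites losing every channel are removed from both the table and the truth
#' table, whose keys always match the emitted sites exactly.
#'
#' The truth table records, per site, the realized true log2 effects of
#' every default comparison (`d_high` = proficient/deficient in high serum,
#' `d_low` = same in low serum, `x`/`y` = serum-withdrawal responses in
#' proficient/deficient cells), the planted serum class, the differential
#' flag and the planted kinase-set membership. Note the anchored design has
#' three free condition effects, so `d_low = d_high + y - x` by
#' construction.
#'
#' @param config a [synthetic_config()].
#' @param design a [silac_design()]; channels are generated for every
#'   assigned `(set, channel)` slot.
#' @return list with `sites` (a `phospho_sites` data.frame) and `truth`.
#' @export
generate_phosphoproteome <- function(config, design = default_design()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, 1L))

  n_prot <- config$n_proteins
  genes <- sprintf("Gene%04d", seq_len(n_prot))
  prots <- sprintf("P%05d", seq_len(n_prot))
  n_sites_per <- 1L + stats::rpois(n_prot, max(0, config$sites_per_protein - 1))
  prot_idx <- rep.int(seq_len(n_prot), n_sites_per)
  n <- length(prot_idx)

  aa <- sample(c("S", "T", "Y"), n, replace = TRUE, prob = c(0.86, 0.12, 0.02))
  pos <- unlist(lapply(n_sites_per, function(m) sample.int(2000L, m)),
                use.names = FALSE)
  residue <- format_residue(aa, pos)

  base <- stats::rnorm(n, config$log2_intensity_mean, config$log2_intensity_sd)

  ## genotype effect on log2(proficient / deficient)
  is_diff <- stats::runif(n) < config$pi_diff
  d1 <- numeric(n)
  d1[is_diff] <- sample(c(-1, 1), sum(is_diff), replace = TRUE) *
    abs(stats::rnorm(sum(is_diff), config$effect_mean, config$effect_sd))

  ## serum-response class and true (x, y)
  probs <- config$serum_props[c("correlated", "persistent_in_deficient",
                                "lost_in_deficient")]
  cls <- sample(c(names(probs), "null"), n, replace = TRUE,
                prob = c(probs, 1 - sum(probs)))
  s <- config$serum_effect
  x <- ifelse(cls == "correlated", s, ifelse(cls == "persistent_in_deficient", s, 0))
  y <- ifelse(cls == "correlated", s, ifelse(cls == "lost_in_deficient", s, 0))

  ## planted kinase-target sets shift the genotype effect of their members
  kin_set <- rep(NA_character_, n)
  if (config$kinase_n_planted > 0L) {
    need <- config$kinase_n_planted * config$kinase_set_size
    if (need > n) config_error("kinase sets larger than the site universe")
    picked <- sample.int(n, need)
    for (i in seq_len(config$kinase_n_planted)) {
      idx <- picked[((i - 1L) * config$kinase_set_size + 1L):
                      (i * config$kinase_set_size)]
      kin_set[idx] <- sprintf("PLANTED_KIN%d", i)
      d1[idx] <- d1[idx] + config$kinase_delta
    }
  }

  ## condition effects relative to the anchor (proficient, high serum)
  effects <- list(
    proficient_high = numeric(n),
    deficient_high  = -d1,
    proficient_low  = -x,
    deficient_low   = -d1 - y
  )

  sd_chan <- noise_sd(config, base)
  sites <- data.frame(
    site_id = sprintf("site%05d", seq_len(n)),
    protein_id = prots[prot_idx],
    gene = genes[prot_idx],
    residue = residue,
    localization_prob = round(stats::rbeta(n, 8, 0.6), 4L),
    stringsAsFactors = FALSE
  )
  for (col in intensity_columns()) sites[[col]] <- NA_real_
  asg <- design$assignments
  for (r in seq_len(nrow(asg))) {
    cond <- asg$condition[r]
    if (!cond %in% names(effects)) {
      config_error(paste0("no synthetic effect model for condition '", cond, "'"))
    }
    eps <- stats::rnorm(n, 0, sd_chan)
    sites[[intensity_col(asg$set[r], asg$channel[r])]] <-
      2^(base + effects[[cond]] + eps)
  }
  if (config$missing_rate > 0) {
    for (r in seq_len(nrow(asg))) {
      col <- intensity_col(asg$set[r], asg$channel[r])
      drop <- stats::runif(n) < config$missing_rate
      sites[[col]][drop] <- NA_real_
    }
  }
  im <- as.matrix(sites[intensity_columns()])
  keep <- rowSums(!is.na(im)) > 0L
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("phospho_sites", "data.frame")

  truth <- data.frame(
    site_id = sprintf("site%05d", seq_len(n)),
    gene = genes[prot_idx],
    residue = residue,
    key = site_key(genes[prot_idx], residue),
    class = cls,
    diff = is_diff,
    d_high = d1,
    d_low = d1 + y - x,
    x = x,
    y = y,
    kinase_set = kin_set,
    base_log2_intensity = base,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(truth) <- NULL

  list(sites = sites, truth = truth)
}

#' Generate a kinase-substrate table with planted enriched sets
#'
#' Planted sets re-emit the members chosen (and shifted) by
#' [generate_phosphoproteome()]; decoy sets sample members uniformly from
#' the emitted site universe with no shift. A handful of same-substrate
#' records under a different species label is included so the species filter
#' of [read_kinase_substrates()] has something to remove.
#'
#' @param config the same [synthetic_config()] used for the site table.
#' @param truth the truth table returned by [generate_phosphoproteome()].
#' @return list with `table` (kinase-substrate records) and `truth`
#'   (`planted`, `decoys`, `membership`).
#' @export
generate_kinase_substrates <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, 2L))
  rows <- list()
  membership <- list()
  planted <- sort(unique(truth$kinase_set[!is.na(truth$kinase_set)]))
  for (kin in planted) {
    m <- truth[!is.na(truth$kinase_set) & truth$kinase_set == kin, ]
    rows[[kin]] <- data.frame(kinase = kin, species_kinase = "mouse",
                              substrate_gene = m$gene,
                              species_substrate = "mouse",
                              residue = m$residue, stringsAsFactors = FALSE)
    membership[[kin]] <- m$key
  }
  decoys <- sprintf("DECOY_KIN%02d", seq_len(config$kinase_n_decoy))
  for (kin in decoys) {
    idx <- sample.int(nrow(truth), min(config$kinase_set_size, nrow(truth)))
    rows[[kin]] <- data.frame(kinase = kin, species_kinase = "mouse",
                              substrate_gene = truth$gene[idx],
                              species_substrate = "mouse",
                              residue = truth$residue[idx],
                              stringsAsFactors = FALSE)
    membership[[kin]] <- truth$key[idx]
  }
  tab <- do.call(rbind, rows)
  ## off-species records that the reader must filter out
  n_off <- min(10L, nrow(tab))
  off <- tab[sample.int(nrow(tab), n_off), ]
  off$species_substrate <- "human"
  tab <- rbind(tab, off)
  rownames(tab) <- NULL
  list(table = tab,
       truth = list(planted = planted, decoys = decoys,
                    membership = membership))
}

#' Generate annotation sets and a scored interaction network
#'
#' Plants `module_count` disjoint protein modules, each carrying one
#' dedicated annotation term and densely connected by edges scoring above
#' 0.9 (with probability `module_edge_prob` per pair); background terms are
#' random draws from the protein universe and background edges score below
#' 0.9. The emitted edge list is canonical (see [read_edges()]).
#'
#' @param config a [synthetic_config()].
#' @param proteins character vector of protein symbols (the gene universe
#'   of the generated site table).
#' @return list with `annotations` (an [annotation_map()]), `edges` and
#'   `truth` (`modules`, `module_terms`).
#' @export
generate_annotations_and_network <- function(config, proteins) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, 3L))
  proteins <- sort(unique(as.character(proteins)))
  P <- length(proteins)
  need <- config$module_count * config$module_size
  if (need > P) config_error("modules larger than the protein universe")
  picked <- sample(proteins, need)
  modules <- split(picked, rep(seq_len(config$module_count),
                               each = config$module_size))
  modules <- lapply(modules, sort)
  module_terms <- sprintf("MODULE_TERM_%d", seq_len(config$module_count))
  names(modules) <- module_terms

  sets <- modules
  for (i in seq_len(config$annotation_n_terms)) {
    sz <- 3L + stats::rpois(1L, 12)
    sets[[sprintf("TERM_%03d", i)]] <- sort(sample(proteins, min(sz, P)))
  }

  edge_rows <- list()
  for (m in seq_along(modules)) {
    mem <- modules[[m]]
    pr <- t(utils::combn(mem, 2L))
    hi <- stats::runif(nrow(pr)) < config$module_edge_prob
    sc <- ifelse(hi,
                 stats::runif(nrow(pr), config$module_score_range[1L],
                              config$module_score_range[2L]),
                 stats::runif(nrow(pr), config$background_score_range[1L],
                              config$background_score_range[2L]))
    edge_rows[[m]] <- data.frame(a = pr[, 1L], b = pr[, 2L], score = sc,
                                 stringsAsFactors = FALSE)
  }
  n_bg <- min(20000L, round(config$background_edge_prob * choose(P, 2L)))
  if (n_bg > 0L) {
    ia <- sample.int(P, n_bg, replace = TRUE)
    ib <- sample.int(P, n_bg, replace = TRUE)
    ok <- ia != ib
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      a = proteins[ia[ok]], b = proteins[ib[ok]],
      score = stats::runif(sum(ok), config$background_score_range[1L],
                           config$background_score_range[2L]),
      stringsAsFactors = FALSE)
  }
  edges <- canonical_edges(do.call(rbind, edge_rows))
  list(annotations = annotation_map(sets, background = proteins),
       edges = edges,
       truth = list(modules = modules, module_terms = module_terms))
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper: site table + truth, kinase-substrate table + truth,
#' annotations and network + truth, all from one configuration.
#'
#' @inheritParams generate_phosphoproteome
#' @return list with `sites`, `truth`, `kinase`, `kinase_truth`,
#'   `annotations`, `edges`, `network_truth`.
#' @export
generate_study <- function(config, design = default_design()) {
  phos <- generate_phosphoproteome(config, design)
  kin <- generate_kinase_substrates(config, phos$truth)
  net <- generate_annotations_and_network(config, unique(phos$sites$gene))
  list(sites = phos$sites, truth = phos$truth,
       kinase = kin$table, kinase_truth = kin$truth,
       annotations = net$annotations, edges = net$edges,
       network_truth = net$truth)
}
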