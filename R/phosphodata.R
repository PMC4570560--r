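## Domain model and table I/O: phosphosite quantification tables,
## kinase-substrate tables, scored edge lists, GMT annotation maps, and the
## experiment design linking SILAC channels to biological conditions.

SETS <- c(1L, 2L)
CHANNELS <- c("light", "medium", "heavy")

intensity_columns <- function() {
  as.vector(outer(SETS, CHANNELS, function(s, ch) paste0("int_set", s, "_", ch)))
}

SITE_COLUMNS <- c("site_id", "protein_id", "gene", "residue",
                  "localization_prob", intensity_columns())

#' Column dialect for phosphosite tables
#'
#' Maps the canonical column names used throughout the package to the column
#' headers found in a particular file. The default is the identity mapping on
#' the package's own tab-separated layout (the upstream search engine versions
#' its column names, so a dialect keeps the reader stable across layouts).
#' Files are tab-separated, UTF-8, with `.` as the decimal mark.
#'
#' @param ... named overrides, `canonical = "file column"`.
#' @return named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' site_dialect(gene = "Gene names", residue = "Position in protein")
site_dialect <- function(...) {
  d <- stats::setNames(SITE_COLUMNS, SITE_COLUMNS)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), SITE_COLUMNS)
    if (length(bad)) {
      config_error(paste0("unknown dialect field(s): ", paste(bad, collapse = ", ")))
    }
    d[names(over)] <- over
  }
  d
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  if (file.size(path) == 0L) {
    return(NULL)
  }
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    na.strings = c("NA", ""))
}

empty_site_table <- function() {
  df <- as.data.frame(stats::setNames(
    c(list(character(), character(), character(), character(), numeric()),
      rep(list(numeric()), 6L)),
    SITE_COLUMNS))
  class(df) <- c("phospho_sites", "data.frame")
  df
}

#' Read a phosphosite quantification table
#'
#' One row per quantified phosphosite: protein accession, gene symbol,
#' residue (`S`/`T`/`Y` + 1-based position), optional localization
#' probability, and per-channel intensities for up to two triple-SILAC
#' experiment sets. Rows failing validation (malformed residue, no usable
#' intensity, localization probability outside `[0, 1]`, duplicate
#' `site_id`) are dropped and counted in the load report attached as
#' `attr(x, "load_report")`. Zero intensities are treated as missing at load:
#' a zero is a failed quantification and would corrupt log-ratio and binning
#' statistics downstream.
#'
#' Localization probability is carried but not filtered on by default;
#' `min_localization` enables the conventional >= 0.75 class-I cutoff.
#'
#' @param path file path to a tab-separated site table.
#' @param dialect column mapping from [site_dialect()].
#' @param min_localization optional lower bound on localization probability;
#'   rows below it are dropped (and counted). `NULL` (default) keeps all.
#' @return a `phospho_sites` data.frame with canonical columns and a
#'   `load_report` attribute (`kept`, `dropped`, `reasons`).
#' @export
read_site_table <- function(path, dialect = site_dialect(),
                            min_localization = NULL) {
  raw <- read_tsv_raw(path)
  if (is.null(raw) || nrow(raw) == 0L) {
    warning("empty site table: ", path)
    out <- empty_site_table()
    attr(out, "load_report") <- list(kept = 0L, dropped = 0L,
                                     reasons = integer())
    return(out)
  }
  mandatory <- c("site_id", "protein_id", "gene", "residue")
  for (col in mandatory) {
    if (!dialect[[col]] %in% names(raw)) {
      format_error(paste0("missing mandatory column: ", dialect[[col]]))
    }
  }
  int_cols <- intensity_columns()
  present_int <- int_cols[dialect[int_cols] %in% names(raw)]
  if (!length(present_int)) {
    format_error("missing mandatory column: at least one intensity column")
  }

  df <- data.frame(
    site_id = as.character(raw[[dialect[["site_id"]]]]),
    protein_id = as.character(raw[[dialect[["protein_id"]]]]),
    gene = as.character(raw[[dialect[["gene"]]]]),
    residue = as.character(raw[[dialect[["residue"]]]]),
    stringsAsFactors = FALSE
  )
  lp_col <- dialect[["localization_prob"]]
  df$localization_prob <- if (lp_col %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[lp_col]]))
  } else {
    NA_real_
  }
  for (col in int_cols) {
    df[[col]] <- if (col %in% present_int) {
      v <- suppressWarnings(as.numeric(raw[[dialect[[col]]]]))
      v[!is.na(v) & v == 0] <- NA_real_  # zero intensity == missing
      v
    } else {
      NA_real_
    }
  }

  reasons <- c(bad_residue = 0L, negative_intensity = 0L, no_intensity = 0L,
               bad_localization = 0L, duplicate_site_id = 0L,
               low_localization = 0L)
  im <- as.matrix(df[int_cols])
  bad_res <- !is_valid_residue(df$residue)
  neg_int <- apply(im, 1L, function(r) any(!is.na(r) & r < 0))
  no_int <- rowSums(!is.na(im)) == 0L
  bad_lp <- !is.na(df$localization_prob) &
    (df$localization_prob < 0 | df$localization_prob > 1)
  dup <- duplicated(df$site_id)
  low_lp <- if (is.null(min_localization)) rep(FALSE, nrow(df)) else {
    !is.na(df$localization_prob) & df$localization_prob < min_localization
  }
  reasons["bad_residue"] <- sum(bad_res)
  reasons["negative_intensity"] <- sum(neg_int & !bad_res)
  reasons["no_intensity"] <- sum(no_int & !bad_res & !neg_int)
  reasons["bad_localization"] <- sum(bad_lp & !bad_res & !neg_int & !no_int)
  reasons["duplicate_site_id"] <-
    sum(dup & !bad_res & !neg_int & !no_int & !bad_lp)
  drop <- bad_res | neg_int | no_int | bad_lp | dup
  reasons["low_localization"] <- sum(low_lp & !drop)
  drop <- drop | low_lp

  out <- df[!drop, SITE_COLUMNS, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phospho_sites", "data.frame")
  attr(out, "load_report") <- list(kept = nrow(out), dropped = sum(drop),
                                   reasons = reasons)
  out
}

#' Write a phosphosite table
#'
#' Deterministic canonical column order, tab-separated, lossless for all
#' fields; two writes of the same collection are byte-identical.
#' [read_site_table()] of the result reproduces the input field-by-field.
#'
#' @param x a `phospho_sites` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  missing_cols <- setdiff(SITE_COLUMNS, names(x))
  if (length(missing_cols)) {
    format_error(paste0("site table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  write_tsv(x[SITE_COLUMNS], path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  for (col in names(df)[num]) {
    v <- df[[col]]
    out <- vapply(v, function(z) {
      if (is.na(z)) NA_character_ else format(z, digits = 17, scientific = FALSE)
    }, character(1L))
    df[[col]] <- out
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

KINASE_COLUMNS <- c("kinase", "species_kinase", "substrate_gene",
                    "species_substrate", "residue")

#' Read a kinase-substrate table
#'
#' Flat tab-separated table with columns `kinase`, `species_kinase`,
#' `substrate_gene`, `species_substrate`, `residue`. Only records whose
#' kinase AND substrate species both equal `species` are kept, i.e. residues
#' annotated as phosphorylated by a kinase of the requested organism in cells
#' of that organism. Rows with a malformed residue are dropped with a
#' warning.
#'
#' @param path file path.
#' @param species species label to keep on both sides (case-insensitive);
#'   default `"mouse"`.
#' @return data.frame of kinase-target records; `load_report` attribute
#'   counts filtered rows.
#' @export
read_kinase_substrates <- function(path, species = "mouse") {
  raw <- read_tsv_raw(path)
  if (is.null(raw) || nrow(raw) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character()), 5L),
                                         KINASE_COLUMNS))
    attr(out, "load_report") <- list(kept = 0L, dropped_residue = 0L,
                                     dropped_species = 0L)
    return(out)
  }
  for (col in KINASE_COLUMNS) {
    if (!col %in% names(raw)) format_error(paste0("missing mandatory column: ", col))
  }
  df <- raw[KINASE_COLUMNS]
  for (col in KINASE_COLUMNS) df[[col]] <- as.character(df[[col]])
  if (any(is.na(df$species_kinase) | df$species_kinase == "") ||
      any(is.na(df$species_substrate) | df$species_substrate == "")) {
    format_error("empty species label in kinase-substrate table")
  }
  bad_res <- !is_valid_residue(df$residue)
  if (any(bad_res)) {
    warning(sum(bad_res), " kinase-substrate row(s) with malformed residue dropped")
  }
  keep_species <- tolower(df$species_kinase) == tolower(species) &
    tolower(df$species_substrate) == tolower(species)
  out <- df[!bad_res & keep_species, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "load_report") <- list(
    kept = nrow(out),
    dropped_residue = sum(bad_res),
    dropped_species = sum(!keep_species & !bad_res)
  )
  out
}

#' @rdname read_kinase_substrates
#' @param x data.frame of kinase-target records.
#' @export
write_kinase_substrates <- function(x, path) {
  write_tsv(x[KINASE_COLUMNS], path)
}

#' Read a scored protein-protein edge list
#'
#' Tab-separated columns `a`, `b`, `score` with confidence scores in
#' `[0, 1]` (a score outside that range is a format error). Edges are
#' undirected: endpoint order is canonicalized and duplicate edges collapse
#' to the maximum score. Self-edges are dropped with a warning.
#'
#' @param path file path.
#' @return data.frame with columns `a`, `b`, `score`.
#' @export
read_edges <- function(path) {
  raw <- read_tsv_raw(path)
  if (is.null(raw) || nrow(raw) == 0L) {
    return(data.frame(a = character(), b = character(), score = numeric()))
  }
  for (col in c("a", "b", "score")) {
    if (!col %in% names(raw)) format_error(paste0("missing mandatory column: ", col))
  }
  edges <- data.frame(a = as.character(raw$a), b = as.character(raw$b),
                      score = suppressWarnings(as.numeric(raw$score)),
                      stringsAsFactors = FALSE)
  if (any(is.na(edges$score) | edges$score < 0 | edges$score > 1)) {
    format_error("edge score outside [0, 1]")
  }
  canonical_edges(edges)
}

canonical_edges <- function(edges) {
  self <- edges$a == edges$b
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  edges$a <- lo
  edges$b <- hi
  o <- order(edges$a, edges$b, -edges$score)
  edges <- edges[o, , drop = FALSE]
  dup <- duplicated(paste(edges$a, edges$b, sep = "\r"))
  edges <- edges[!dup, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' @rdname read_edges
#' @param x edge data.frame with columns `a`, `b`, `score`.
#' @export
write_edges <- function(x, path) {
  write_tsv(x[c("a", "b", "score")], path)
}

#' Annotation maps (term -> proteins)
#'
#' An annotation map couples a named list of term member sets with a
#' background universe. Every annotated protein must belong to the
#' background and no term may be empty.
#'
#' @param sets named list of character vectors (term -> member symbols).
#' @param background character vector of background protein symbols;
#'   defaults to the union of all members.
#' @return an `annotation_map` object (list with `sets`, `background`).
#' @export
annotation_map <- function(sets, background = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    format_error("annotation terms must be named")
  }
  sets <- lapply(sets, function(m) sort(unique(as.character(m))))
  if (any(lengths(sets) == 0L)) format_error("empty annotation term")
  if (is.null(background)) background <- sort(unique(unlist(sets)))
  background <- sort(unique(as.character(background)))
  stray <- setdiff(unlist(sets), background)
  if (length(stray)) {
    value_error(paste0("annotated proteins outside background: ",
                       paste(utils::head(stray, 5L), collapse = ", ")))
  }
  structure(list(sets = sets, background = background),
            class = "annotation_map")
}

#' Read annotations in GMT format
#'
#' One term per line: `term<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path to a GMT file.
#' @inheritParams annotation_map
#' @return an `annotation_map`.
#' @export
read_annotations <- function(path, background = NULL) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    format_error("GMT line with fewer than 3 fields (term, description, members)")
  }
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  annotation_map(sets, background = background)
}

#' @rdname read_annotations
#' @param x an `annotation_map`.
#' @param descriptions optional named character vector of term descriptions.
#' @export
write_annotations <- function(x, path, descriptions = NULL) {
  stopifnot(inherits(x, "annotation_map"))
  lines <- vapply(names(x$sets), function(tm) {
    desc <- if (!is.null(descriptions) && tm %in% names(descriptions)) {
      descriptions[[tm]]
    } else {
      "na"
    }
    paste(c(tm, desc, x$sets[[tm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Experiment design for anchored triple-SILAC sets
#'
#' Describes which biological condition each `(set, channel)` pair measures,
#' which condition is the anchor shared by both sets (the reference grown in
#' light label and measured in both experiments, allowing cross-set ratio
#' chaining), and the named condition comparisons of interest. A comparison
#' whose two conditions live in one set is "direct"; otherwise its ratio is
#' composed through the anchor.
#'
#' @param assignments list named `"1"`/`"2"`, each a named character vector
#'   `channel = condition` with channels among light/medium/heavy.
#' @param anchor condition label present in both sets.
#' @param comparisons named list of length-2 character vectors
#'   `c(first, second)`; ratios are `log2(first / second)`.
#' @return a `silac_design` object.
#' @export
#' @examples
#' default_design()
silac_design <- function(assignments, anchor, comparisons) {
  if (!all(names(assignments) %in% c("1", "2"))) {
    config_error("assignments must be named '1' and '2'")
  }
  rows <- do.call(rbind, lapply(names(assignments), function(s) {
    a <- assignments[[s]]
    if (!all(names(a) %in% CHANNELS)) {
      config_error("channels must be among light/medium/heavy")
    }
    data.frame(set = as.integer(s), channel = names(a),
               condition = unname(a), stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(rows[c("set", "channel")])) {
    config_error("duplicate (set, channel) assignment")
  }
  for (s in unique(rows$set)) {
    if (!anchor %in% rows$condition[rows$set == s]) {
      config_error(paste0("anchor condition '", anchor,
                          "' is not assigned in set ", s))
    }
  }
  if (is.null(names(comparisons)) || any(names(comparisons) == "")) {
    config_error("comparisons must be named")
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    if (length(cmp) != 2L) config_error("each comparison needs two conditions")
    for (cond in cmp) {
      if (!cond %in% rows$condition) {
        config_error(paste0("comparison '", nm, "' references unassigned condition '",
                            cond, "'"))
      }
    }
  }
  structure(list(assignments = rows, anchor = anchor,
                 comparisons = lapply(comparisons, unname)),
            class = "silac_design")
}

#' @rdname silac_design
#' @export
default_design <- function() {
  silac_design(
    assignments = list(
      `1` = c(light = "proficient_high", medium = "deficient_high"),
      `2` = c(light = "proficient_high", medium = "proficient_low",
              heavy = "deficient_low")
    ),
    anchor = "proficient_high",
    comparisons = list(
      smarcb1_high     = c("proficient_high", "deficient_high"),
      smarcb1_low      = c("proficient_low", "deficient_low"),
      serum_proficient = c("proficient_high", "proficient_low"),
      serum_deficient  = c("deficient_high", "deficient_low")
    )
  )
}

#' @export
print.silac_design <- function(x, ...) {
  cat("silac_design: anchor =", x$anchor, "\n")
  print(x$assignments, row.names = FALSE)
  cat("comparisons:\n")
  for (nm in names(x$comparisons)) {
    cat(sprintf("  %s: %s vs %s\n", nm, x$comparisons[[nm]][1L],
                x$comparisons[[nm]][2L]))
  }
  invisible(x)
}

design_slot <- function(design, condition, set = NULL) {
  rows <- design$assignments
  hit <- rows[rows$condition == condition, , drop = FALSE]
  if (!is.null(set)) hit <- hit[hit$set == set, , drop = FALSE]
  hit
}

intensity_col <- function(set, channel) paste0("int_set", set, "_", channel)
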