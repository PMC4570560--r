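test_that("residue parsing is a bijection on valid strings and rejects the rest", {
  set.seed(11)
  aa <- sample(c("S", "T", "Y"), 200, replace = TRUE)
  pos <- sample.int(5000, 200, replace = TRUE)
  s <- format_residue(aa, pos)
  parsed <- parse_residue(s)
  expect_identical(parsed$aa, aa)
  expect_identical(parsed$pos, as.integer(pos))
  expect_identical(format_residue(parsed$aa, parsed$pos), s)

  bad <- c("A123", "S0", "S-1", "s12", "T", "12", "", NA, "Y12.5")
  expect_true(all(is.na(parse_residue(bad)$aa)))
  expect_false(any(is_valid_residue(bad)))
})

test_that("site tables round-trip through write/read field-by-field", {
  study <- generate_phosphoproteome(quick_config(101))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(study$sites, path)
  back <- read_site_table(path)
  expect_identical(attr(back, "load_report")$dropped, 0L)
  expect_equal(as.data.frame(back), as.data.frame(study$sites),
               tolerance = 1e-12, ignore_attr = TRUE)

  # deterministic bytes: two writes of the same collection are identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(study$sites, path2)
  expect_identical(unname(tools::md5sum(path)), unname(tools::md5sum(path2)))
})

test_that("site reader validates rows, drops and counts failures", {
  sites <- make_sites(
    list(gene = "Egfr", residue = "T695", int_set1_light = 1000,
         int_set1_medium = 250, int_set2_light = 900),
    list(gene = "Bad1", residue = "X99", int_set1_light = 10),
    list(gene = "Bad2", residue = "S10"),                      # no intensity
    list(gene = "Bad3", residue = "S11", int_set1_light = -5), # negative
    list(gene = "Zero", residue = "S12", int_set1_light = 0,
         int_set1_medium = 40)                                 # zero -> NA
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites, path)
  got <- read_site_table(path)
  rep <- attr(got, "load_report")
  expect_identical(rep$kept, 2L)
  expect_identical(rep$dropped, 3L)
  expect_identical(unname(rep$reasons["bad_residue"]), 1L)
  expect_identical(unname(rep$reasons["no_intensity"]), 1L)
  expect_identical(unname(rep$reasons["negative_intensity"]), 1L)
  # Egfr T695 parses to (T, 695); zero intensity became missing
  egfr <- got[got$gene == "Egfr", ]
  expect_identical(parse_residue(egfr$residue)$aa, "T")
  expect_identical(parse_residue(egfr$residue)$pos, 695L)
  expect_true(is.na(got[got$gene == "Zero", "int_set1_light"]))
})

test_that("empty and malformed site files are handled", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(got <- read_site_table(empty), "empty")
  expect_identical(nrow(got), 0L)
  expect_identical(attr(got, "load_report")$kept, 0L)

  headers_only <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(make_sites()[0, ], headers_only)
  expect_warning(got2 <- read_site_table(headers_only), "empty")
  expect_identical(nrow(got2), 0L)

  noresidue <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site_id\tprotein_id\tgene\tint_set1_light",
               "s1\tP1\tG1\t10"), noresidue)
  expect_error(read_site_table(noresidue), "residue",
               class = "silac_format_error")
})

test_that("site dialects remap columns and localization filter is opt-in", {
  sites <- make_sites(
    list(gene = "Pxn", residue = "Y118", int_set1_light = 10,
         int_set1_medium = 20, localization_prob = 0.5),
    list(gene = "Vcl", residue = "S290", int_set1_light = 5,
         int_set1_medium = 2, localization_prob = 0.99)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites, path)
  txt <- readLines(path)
  txt[1] <- sub("\\bgene\\b", "Gene names", txt[1])
  writeLines(txt, path)
  expect_error(read_site_table(path), "gene", class = "silac_format_error")
  got <- read_site_table(path, dialect = site_dialect(gene = "Gene names"))
  expect_identical(got$gene, c("Pxn", "Vcl"))
  # default keeps low-localization rows; the 0.75 cutoff drops them
  strict <- read_site_table(path, dialect = site_dialect(gene = "Gene names"),
                            min_localization = 0.75)
  expect_identical(strict$gene, "Vcl")
})

test_that("kinase-substrate reader keeps only same-species records", {
  tab <- data.frame(
    kinase = c("Akt1", "AKT1", "Akt1", "Mapk1"),
    species_kinase = c("mouse", "human", "mouse", "mouse"),
    substrate_gene = c("Gsk3b", "GSK3B", "Bad", "Jun"),
    species_substrate = c("mouse", "human", "human", "mouse"),
    residue = c("S9", "S9", "S155", "S246"),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kinase_substrates(tab, path)
  got <- read_kinase_substrates(path, species = "mouse")
  expect_identical(nrow(got), 2L)
  expect_setequal(got$substrate_gene, c("Gsk3b", "Jun"))
  expect_identical(attr(got, "load_report")$dropped_species, 2L)

  # malformed residue rows are dropped with a warning
  tab$residue[4] <- "Q1"
  write_kinase_substrates(tab, path)
  expect_warning(got2 <- read_kinase_substrates(path, species = "mouse"),
                 "malformed")
  expect_identical(got2$substrate_gene, "Gsk3b")

  # generated table: kept count equals the planted mouse/mouse count
  study <- generate_phosphoproteome(quick_config(7))
  kin <- generate_kinase_substrates(quick_config(7), study$truth)
  write_kinase_substrates(kin$table, path)
  got3 <- read_kinase_substrates(path, species = "mouse")
  expect_identical(nrow(got3),
                   sum(tolower(kin$table$species_kinase) == "mouse" &
                       tolower(kin$table$species_substrate) == "mouse"))
})

test_that("edge lists canonicalize, collapse duplicates and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\tscore", "A\tB\t0.8", "B\tA\t0.95", "C\tC\t0.5",
               "A\tC\t0.3"), path)
  expect_warning(got <- read_edges(path), "self-edge")
  expect_identical(nrow(got), 2L)
  ab <- got[got$a == "A" & got$b == "B", ]
  expect_equal(ab$score, 0.95)

  writeLines(c("a\tb\tscore", "A\tB\t1.5"), path)
  expect_error(read_edges(path), "score", class = "silac_format_error")

  net <- generate_annotations_and_network(quick_config(5),
                                          sprintf("Gene%04d", 1:100))
  write_edges(net$edges, path)
  expect_equal(read_edges(path), net$edges, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("annotation maps validate membership and round-trip through GMT", {
  expect_error(annotation_map(list(T1 = character())), "empty",
               class = "silac_format_error")
  expect_error(annotation_map(list(T1 = c("A", "B")), background = "A"),
               "outside background", class = "silac_value_error")
  amap <- annotation_map(list(T1 = c("A", "B"), T2 = "C"),
                         background = c("A", "B", "C", "D"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_annotations(amap, path)
  back <- read_annotations(path, background = amap$background)
  expect_identical(back$sets, amap$sets)
  expect_identical(back$background, amap$background)
})

test_that("experiment designs validate the anchor and comparisons", {
  expect_error(
    silac_design(list(`1` = c(light = "a"), `2` = c(light = "b")),
                 anchor = "a", comparisons = list(c1 = c("a", "b"))),
    "anchor", class = "silac_config_error")
  expect_error(
    silac_design(list(`1` = c(light = "a", medium = "b"),
                      `2` = c(light = "a")),
                 anchor = "a", comparisons = list(c1 = c("b", "zz"))),
    "unassigned", class = "silac_config_error")
  d <- default_design()
  expect_s3_class(d, "silac_design")
  expect_true(all(vapply(1:2, function(s) {
    d$anchor %in% d$assignments$condition[d$assignments$set == s]
  }, logical(1))))
})
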