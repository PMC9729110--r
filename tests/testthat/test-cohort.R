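# Catalog parsing, impact classification, validation, rank statistics.

test_that("protein-change strings parse and filter as documented", {
  df <- tibble::tibble(
    protein_change = c("p.G375R", "p.L509L", "p.R123C", "not_a_change",
                       "p.A12*", "p.W89G"),
    stage = c("Stage IV", "Stage I", "Stage IIIA", "II", NA, "Metastatic")
  )
  expect_message(rec <- parse_mutation_catalog(df), "skipped 2 unparsable and 1 synonymous")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$position, c(375L, 123L, 89L))
  expect_equal(rec$wt, c("G", "R", "W"))
  expect_equal(rec$mut, c("R", "C", "G"))
  expect_equal(as.character(rec$stage), c("IV", "III", "UNKNOWN"))
  expect_equal(attr(rec, "skipped")$n, c(2L, 1L))
})

test_that("catalog files round-trip through CSV and TSV", {
  df <- tibble::tibble(position = c(5L, 9L), wt = c("A", "G"),
                       mut = c("W", "R"), stage = c("I", "IV"))
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, fcsv, row.names = FALSE)
  rec <- parse_mutation_catalog(fcsv)
  expect_equal(rec$protein_change, c("p.A5W", "p.G9R"))
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, ftsv, sep = "\t", row.names = FALSE)
  expect_equal(nrow(parse_mutation_catalog(ftsv)), 2L)
  expect_error(parse_mutation_catalog(tibble::tibble(a = 1)),
               class = "porescreen_schema_error")
})

test_that("stage normalization collapses sub-stages and unknowns", {
  expect_equal(
    as.character(normalize_stage(c("Stage IA", "stage iib", "III", "4",
                                   "Stage X", NA, "IV"))),
    c("I", "II", "III", "IV", "UNKNOWN", "UNKNOWN", "IV")
  )
})

test_that("site resolution demands a wild-type match", {
  rt <- toy_residues()
  rec <- tibble::tibble(position = c(1L, 2L, 9999L), wt = c("A", "R", "A"),
                        mut = c("W", "C", "G"))
  expect_message(out <- resolve_catalog_sites(rt$structure, rec), "not resolved")
  expect_equal(out$site_resolved, c(TRUE, FALSE, FALSE))
  expect_equal(out$key[1], "A:1")
})

test_that("impact classification applies the neutral band symmetrically", {
  expect_equal(as.character(classify_impact(2.0, 1.4, 0.05)), "close")
  expect_equal(as.character(classify_impact(2.0, 2.0, 0.2)), "neutral")
  expect_equal(as.character(classify_impact(2.0, 2.04, 0.05)), "neutral")
  expect_equal(as.character(classify_impact(2.0, 2.06, 0.05)), "open")
  # antisymmetry: swapping wt and mut swaps close and open
  wt <- c(2, 2, 2); mut <- c(1.5, 2.01, 2.7)
  fwd <- classify_impact(wt, mut, 0.05)
  rev <- classify_impact(mut, wt, 0.05)
  expect_equal(as.character(fwd), c("close", "neutral", "open"))
  expect_equal(as.character(rev), c("open", "neutral", "close"))
  expect_error(classify_impact(-1, 2, 0.05), class = "porescreen_input_error")
  # epsilon = 0 reproduces a strict sign rule
  expect_equal(as.character(classify_impact(2, 1.999999, 0)), "close")
})

test_that("closed-fraction summary partitions the calls", {
  calls <- tibble::tibble(
    label = factor(c(rep("close", 6), rep("open", 3), "neutral"),
                   levels = c("close", "neutral", "open")),
    site_resolved = TRUE
  )
  s <- summarize_closed_fraction(calls)
  expect_equal(s$n_close + s$n_neutral + s$n_open, s$n_total)
  expect_equal(s$fraction_closed, 0.6)
  calls0 <- tibble::tibble(label = factor(rep("open", 10),
                                          levels = c("close", "neutral", "open")),
                           site_resolved = TRUE)
  expect_equal(summarize_closed_fraction(calls0)$fraction_closed, 0)
  expect_error(summarize_closed_fraction(calls[0, ]),
               class = "porescreen_input_error")
})

test_that("known-function validation counts concordance and drops absentees", {
  calls <- tibble::tibble(
    position = 1:5, wt = "A", mut = c("W", "F", "G", "S", "L"),
    label = factor(c("open", "open", "open", "close", "close"),
                   levels = c("close", "neutral", "open")),
    site_resolved = TRUE
  )
  known <- tibble::tibble(position = c(1:4, 99L), wt = "A",
                          mut = c("W", "F", "G", "S", "W"),
                          annotation = c("GoF", "GoF", "GoF", "LoF", "GoF"))
  expect_message(v <- validate_known_function(calls, known), "matched no")
  expect_equal(v$n_annotated, 4L)
  expect_equal(v$n_unmatched, 1L)
  expect_equal(v$concordance, 1.0)
  # one discordant annotation drops concordance to 3/4
  known2 <- known[1:4, ]
  known2$annotation[4] <- "GoF"   # a "GoF" that the model calls close
  v2 <- validate_known_function(calls, known2)
  expect_equal(v2$concordance, 0.75)
  expect_equal(sum(v2$confusion[, c("close", "neutral", "open")]), 4L)
})

test_that("Mann-Whitney matches exhaustive label enumeration without ties", {
  m <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(m$U, 0)
  expect_equal(m$p_two_tailed, 1 / 3)
  set.seed(17)
  for (rep in 1:5) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    m <- mann_whitney_u(a, b)
    expect_equal(m$method, "exact")
    expect_equal(m$p_two_tailed, exhaustive_mwu_p(a, b), tolerance = 1e-9)
    # independent reference implementation on the exact no-ties path
    expect_equal(m$p_two_tailed, wilcox.test(a, b)$p.value, tolerance = 1e-9)
    expect_equal(m$U, unname(wilcox.test(a, b)$statistic))
    # symmetry: swapping groups maps U to n_a * n_b - U, same p
    ms <- mann_whitney_u(b, a)
    expect_equal(ms$U, 64 - m$U)
    expect_equal(ms$p_two_tailed, m$p_two_tailed)
  }
})

test_that("Mann-Whitney handles ties and identical groups sensibly", {
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$p_two_tailed, 1)
  expect_equal(mann_whitney_u(rep(3, 10), rep(3, 12))$p_two_tailed, 1)
  # large-sample path is close to the exact one
  set.seed(4)
  a <- rnorm(30); b <- rnorm(30, 1)
  m <- mann_whitney_u(a, b)
  expect_equal(m$method, "normal_approx")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(m$p_two_tailed, ref$p.value, tolerance = 1e-6)
  expect_error(mann_whitney_u(numeric(0), 1), class = "porescreen_input_error")
})

test_that("stage association reports reference comparisons with medians", {
  set.seed(9)
  calls <- tibble::tibble(
    stage = factor(rep(c("I", "II", "IV"), times = c(47, 30, 27)),
                   levels = porescreen:::stage_levels),
    mut_min_radius = c(rnorm(47, 2, 0.2), rnorm(30, 2, 0.2), rnorm(27, 1.5, 0.2)),
    site_resolved = TRUE
  )
  out <- stage_association(calls)
  expect_equal(out$group_a, c("I", "I"))
  expect_equal(out$group_b, c("II", "IV"))
  expect_equal(out$n_a, c(47L, 47L))
  expect_lt(out$p_two_tailed[out$group_b == "IV"], 0.01)
  expect_gt(out$p_two_tailed[out$group_b == "II"], 0.05)
  expect_equal(out$median_a[1], median(calls$mut_min_radius[calls$stage == "I"]))
  # identical values at the study's stage I / IV group sizes give p = 1
  calls_id <- tibble::tibble(
    stage = factor(rep(c("I", "IV"), times = c(47, 27)),
                   levels = porescreen:::stage_levels),
    mut_min_radius = 2, site_resolved = TRUE
  )
  out_id <- stage_association(calls_id)
  expect_equal(out_id$p_two_tailed, 1)
  expect_true(0 <= out_id$U && out_id$U <= 47 * 27)
  # all pairs + Holm on request
  out_all <- stage_association(calls, pairs = "all", adjust = "holm")
  expect_equal(nrow(out_all), 3L)
  expect_true(all(out_all$p_adjusted >= out_all$p_two_tailed))
  expect_error(stage_association(calls_id[1:47, ]),
               class = "porescreen_input_error")
})

test_that("impact pipeline validates planted gain/loss-of-function variants", {
  # wild type: alanine-lined channel with one pore-limiting leucine in the
  # filter ring; shrinking it widens the pore (gain of function), bulky
  # substitutions at neighboring sites narrow it (loss of function)
  rt <- toy_residues()
  wt <- suppressWarnings(mutate_residue(rt$structure, rt$filter_residues[1],
                                        "A", "L"))
  catalog <- tibble::tibble(protein_change = c(
    "p.L25G", "p.L25A", "p.L25S",            # GoF: remove the constriction
    "p.A26W", "p.A27F", "p.A28Y", "p.A29R"   # LoF: add a deeper one
  ))
  records <- parse_mutation_catalog(catalog)
  records <- resolve_catalog_sites(wt, records)
  calls <- suppressWarnings(
    compute_impact(wt, records, rt$filter_residues, axis = c(0, 0, 1),
                   step = 0.5, epsilon = 0.05, seed = 2)
  )
  expect_true(all(calls$site_resolved))
  expect_equal(as.character(calls$label[1:3]), rep("open", 3))
  expect_equal(as.character(calls$label[4:7]), rep("close", 4))
  known <- tibble::tibble(
    position = c(25L, 25L, 25L, 26L, 27L, 28L, 29L),
    wt = c("L", "L", "L", "A", "A", "A", "A"),
    mut = c("G", "A", "S", "W", "F", "Y", "R"),
    annotation = c("GoF", "GoF", "GoF", "LoF", "LoF", "LoF", "LoF")
  )
  v <- validate_known_function(calls, known)
  expect_equal(v$n_annotated, 7L)
  expect_gte(v$concordance, 0.95)
  # deltas carry sign information consistent with the labels
  expect_true(all(calls$delta[1:3] > 0.05))
  expect_true(all(calls$delta[4:7] < -0.05))
})
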