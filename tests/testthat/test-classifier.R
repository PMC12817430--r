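# geography, evidence, decision rules, summaries

test_that("great-circle distance: identity, antipodes, independent oracle", {
  expect_equal(great_circle_km(c(46, 7), c(46, 7)), 0)
  expect_equal(great_circle_km(c(0, 0), c(0, 180)), pi * 6371,
               tolerance = 1e-9)
  a <- c(46.948, 7.447); b <- c(47.377, 8.540)     # two Swiss cities
  expect_equal(great_circle_km(a, b), oracle_great_circle(a, b),
               tolerance = 1e-6)
  expect_error(great_circle_km(c(95, 0), c(0, 0)), "invalid coordinates")
})

test_that("allochthony test applies the strict 100-km rule", {
  refs <- data.frame(esu = c("A", "A", "B"), pop_id = c("r1", "r2", "r3"),
                     lat = c(46.0, 46.5, 47.0), lon = c(7.0, 7.5, 8.0))
  cat <- esu_catalog(rbind(refs, data.frame(esu = "C", pop_id = NA,
                                            lat = NA, lon = NA)))
  expect_equal(cat$autochthonous, c("A", "B"))
  far <- c(48.0, 10.0)                              # > 150 km from any A ref
  near <- c(46.1, 7.1)                              # < 20 km
  expect_equal(allochthony_test(far, "A", cat), "allochthonous")
  expect_equal(allochthony_test(near, "A", cat), "autochthonous")
  # exactly at the threshold: "more than 100 km" keeps it autochthonous
  p <- c(46.9, 7.0)
  d_exact <- min(great_circle_km(matrix(p, 2, 2, byrow = TRUE),
                                 cbind(refs$lat[1:2], refs$lon[1:2])))
  expect_equal(allochthony_test(p, "A", cat, threshold_km = d_exact),
               "autochthonous")
  # no in-region reference populations: allochthonous by definition
  expect_equal(allochthony_test(near, "C", cat), "allochthonous")
  expect_error(allochthony_test(near, "Z", cat), "unknown ESU")
})

test_that("decision rules fire in priority order", {
  # single allochthonous provenance, also admixed -> R1 wins
  r1 <- classify_population(ev("01", "Western Europe",
                               alloch = "Western Europe", admixed = TRUE,
                               homog = TRUE))
  expect_equal(r1$category, "seeded_allochthonous")
  expect_true(r1$direct_seeding)
  # published row examples
  r19 <- classify_population(ev("19", "Eastern Europe",
                                alloch = "Eastern Europe", homog = TRUE))
  expect_equal(r19$category, "seeded_allochthonous")
  r17 <- classify_population(ev("17", c("Central Europe", "Swiss Plateau",
                                        "Western Europe"),
                                alloch = c("Central Europe", "Western Europe"),
                                admixed = TRUE))
  expect_equal(r17$category, "seeded_admixed")
  r24 <- classify_population(ev("24", c("Southern Switzerland", "Swiss Plateau"),
                                admixed = TRUE))
  expect_equal(r24$category, "natural")
  expect_false(r24$direct_seeding)
  # homogeneous autochthonous seed source
  r7 <- classify_population(ev("07", "Swiss Plateau", homog = TRUE))
  expect_equal(r7$category, "seeded_autochthonous_homogeneous")
  # no evidence at all
  expect_equal(classify_population(ev("x", "Swiss Plateau"))$category,
               "natural")
  expect_error(classify_population(ev("y", character())), "empty source")
})

test_that("classification ignores non-genomic evidence entirely", {
  base <- ev("p", "Swiss Plateau", homog = TRUE)
  flipped <- ev("p", "Swiss Plateau", homog = TRUE, collector = TRUE,
                habitat = c(2001, 2005))
  expect_equal(classify_population(base)$category,
               classify_population(flipped)$category)
})

test_that("the packaged fixture loads with the published record counts", {
  fx <- load_evidence_fixture()
  expect_length(fx$evidence, 31)
  expect_equal(sum(vapply(fx$evidence, `[[`, TRUE, "collector_assessment")), 11)
  expect_equal(sum(!vapply(fx$evidence, function(e)
    is.null(e$habitat_modification_period), TRUE)), 9)
  expect_s3_class(fx$catalog, "esu_catalog")
  expect_false("Eastern Europe" %in% fx$catalog$autochthonous)
  # malformed fixtures produce schema errors naming the line
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("pop_id\tlat\tlon\tsources\tsource_kinds\tallochthonous_sources\tadmixed\thomogeneous_evidence\tcollector_flag\thabitat_years",
               "1\t46\t7\tA,B\thomogeneous\t\t0\t0\t0\t"), bad)
  expect_error(load_evidence_fixture(bad), "line 2")
})

test_that("summaries reproduce the published counts and handle edge fixtures", {
  fx <- load_evidence_fixture()
  res <- classify_populations(fx$evidence)
  s <- summarize_seeding(res, fx$evidence)
  expect_equal(s$n_seeded, 15)
  # restricted to the two foreign-provenance populations
  sub <- fx$evidence[c("19", "20")]
  res2 <- classify_populations(sub)
  expect_equal(sum(res2$direct_seeding), 2)
  expect_true(all(res2$category == "seeded_allochthonous"))
  # evidence-free fixture: all natural
  blank <- lapply(paste0("p", 1:5), function(p) ev(p, "A"))
  names(blank) <- paste0("p", 1:5)
  res3 <- classify_populations(blank)
  s3 <- summarize_seeding(res3, blank)
  expect_equal(s3$n_seeded, 0)
  expect_equal(s3$pct_natural, 100)
  # duplicate populations are rejected
  dup <- rbind(res3, res3[1, ])
  expect_error(summarize_seeding(dup, blank), "duplicate")
  # category counts are invariant under population order
  perm <- sample(nrow(res))
  s_perm <- summarize_seeding(res[perm, ], fx$evidence)
  expect_equal(s_perm$n_seeded, s$n_seeded)
  expect_equal(s_perm$pct_allochthonous, s$pct_allochthonous)
})

test_that("build_evidence merges assignments, star groups and range tests", {
  assignments <- data.frame(
    individual_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    esu = c("E1", "E1", "E1", "E1", "E2", "E2"),
    max_foreign_ancestry = c(0.02, 0.01, 0.03, 0.42, 0.01, 0.02),
    admixed = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  metadata <- data.frame(
    individual_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    pop_id = c("PA", "PA", "PB", "PB", "PC", "PC"),
    latitude = c(46, 46, 46.2, 46.2, 48.4, 48.4),
    longitude = c(7, 7, 7.2, 7.2, 10.4, 10.4),
    status = c("natural", "natural", rep("unknown", 4)))
  Q <- rbind(c(0.98, 0.02), c(0.99, 0.01), c(0.97, 0.03),
             c(0.58, 0.42), c(0.01, 0.99), c(0.02, 0.98))
  dimnames(Q) <- list(metadata$individual_id, c("E1", "E2"))
  catalog <- esu_catalog(data.frame(esu = "E1", pop_id = "PA",
                                    lat = 46, lon = 7),
                         esus = c("E1", "E2"))
  report <- structure(list(flagged_pops = "PB"), class = "source_group_report")
  evid <- build_evidence(assignments, metadata, report, catalog, Q = Q)
  expect_equal(evid$PA$source_esus, "E1")
  expect_false(evid$PA$admixed)
  expect_length(evid$PA$allochthonous_sources, 0)
  # PB: one admixed individual contributes both components; flagged group
  expect_setequal(evid$PB$source_esus, c("E1", "E2"))
  expect_true(evid$PB$admixed)
  expect_true(evid$PB$has_homogeneous_source_evidence)
  expect_equal(evid$PB$allochthonous_sources, "E2")   # E2 has no references
  # PC: single source, far away and unbacked -> allochthonous
  expect_equal(evid$PC$allochthonous_sources, "E2")
  expect_error(build_evidence(assignments,
                              metadata[metadata$pop_id != "PC", ],
                              report, catalog, Q = Q),
               "no population mapping")
  # downstream classification of the merged records
  res <- classify_populations(evid)
  expect_equal(res$category[res$pop_id == "PA"], "natural")
  expect_equal(res$category[res$pop_id == "PB"], "seeded_admixed")
  expect_equal(res$category[res$pop_id == "PC"], "seeded_allochthonous")
})
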