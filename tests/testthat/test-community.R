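test_that("isolate table parses with per-tissue counts and derived genera", {
  iso <- monarda_records()
  expect_equal(nrow(iso), 28)
  expect_equal(as.vector(table(iso$tissue)[c("leaf", "root", "flower")]),
               c(18, 2, 8))
  expect_equal(iso$genus[iso$isolate_code == "MC-23 F"], "Gibberella")
  expect_equal(iso$genus[iso$taxon_label == "Fusarium sp."], rep("Fusarium", 2))
})

test_that("tissue is inferred from the isolate-code suffix when absent", {
  path <- write_tsv_fixture(data.frame(
    isolate_code = c("MC-20R", "MC-14 L", "MC-26 F"),
    taxon_label = c("Cladosporium sp.", "Fusarium oxysporum", "Fusarium oxysporum")))
  iso <- read_isolate_table(path)
  expect_equal(iso$tissue, c("root", "leaf", "flower"))
})

test_that("isolate reader validates its input", {
  empty <- write_tsv_fixture(data.frame(isolate_code = character(),
                                        taxon_label = character()))
  expect_equal(nrow(read_isolate_table(empty)), 0)

  dup <- write_tsv_fixture(data.frame(isolate_code = c("A1 L", "A1 L"),
                                      taxon_label = c("X y", "X y")))
  expect_error(read_isolate_table(dup), "duplicate isolate_code")

  nolabel <- write_tsv_fixture(data.frame(isolate_code = "A1 L", other = "x"))
  expect_error(read_isolate_table(nolabel), "missing required column")

  badtissue <- write_tsv_fixture(data.frame(isolate_code = "A1", tissue = "stem",
                                            taxon_label = "X y"))
  expect_error(read_isolate_table(badtissue), "unknown tissue")

  badpct <- write_tsv_fixture(data.frame(isolate_code = "A1 L",
                                         taxon_label = "X y", identity_pct = 120))
  expect_error(read_isolate_table(badpct), "identity_pct")
})

test_that("abundance matrix honours the taxon resolution mode", {
  m <- monarda_matrix("label")
  expect_s3_class(m, "abundance_matrix")
  expect_equal(nrow(m), 23)   # Cladosporium sp., F. oxysporum, Fusarium sp. shared
  expect_equal(unname(colSums(m)), c(18, 2, 8))
  expect_equal(unname(colSums(m > 0)), c(18, 2, 6))
  expect_equal(sort(m[m[, "flower"] > 0, "flower"]), c(1, 1, 1, 1, 1, 3),
               ignore_attr = TRUE)
  expect_true(all(m[m[, "leaf"] > 0, "leaf"] == 1))

  m2 <- monarda_matrix("label_per_tissue")
  expect_equal(nrow(m2), 26)  # taxa never shared across tissues
  expect_gte(nrow(m2), nrow(m))
  expect_equal(unname(colSums(m2)), c(18, 2, 8))
})

test_that("label normalisation merges case/whitespace/period variants", {
  recs <- data.frame(
    isolate_code = c("A1 L", "A2 R", "A3 L", "A4 F"),
    tissue = c("leaf", "root", "leaf", "flower"),
    taxon_label = c("Cladosporium  sp.", "cladosporium sp.",
                    "Fusarium oxysporum.", "Fusarium oxysporum"))
  m <- build_abundance_matrix(recs, "label")
  expect_equal(nrow(m), 2)
  expect_equal(sum(m), 4)
  # "sp." keeps its period; the stray trailing period is stripped
  expect_setequal(rownames(m), c("Cladosporium sp.", "Fusarium oxysporum"))
})

test_that("single record gives a 1x1 matrix with count 1", {
  m <- build_abundance_matrix(data.frame(isolate_code = "A1 L", tissue = "leaf",
                                         taxon_label = "X y"))
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(unname(m[1, 1]), 1L)
  expect_error(build_abundance_matrix(monarda_records()[0, ]), "no records")
})

test_that("relative proportions match the survey and sum to one", {
  m <- monarda_matrix()
  expect_equal(relative_proportion(m, "Fusarium oxysporum"), 4 / 28)
  expect_equal(relative_proportion(m, "Fusarium sp."), 2 / 28)
  expect_error(relative_proportion(m, "Absent taxon"), "unknown taxon")
  total <- sum(vapply(rownames(m), function(t) relative_proportion(m, t), numeric(1)))
  expect_equal(total, 1)
})

test_that("genus frequencies are exact-token fractions within a tissue", {
  m <- monarda_matrix()
  expect_equal(genus_frequency(m, "flower", "Fusarium"), 5 / 8)   # 62.5%
  expect_equal(genus_frequency(m, "leaf", "Aspergillus"), 5 / 18) # ~27%
  expect_equal(genus_frequency(m, "leaf", "Cladosporium"), 2 / 18)
  # anamorph/teleomorph genera are not merged
  expect_equal(genus_frequency(m, "flower", "Gibberella"), 1 / 8)
  expect_error(genus_frequency(m, "stem", "Fusarium"), "unknown tissue")
  for (tissue in colnames(m)) {
    genera <- unique(vapply(strsplit(rownames(m), " "), `[[`, character(1), 1))
    expect_equal(sum(vapply(genera, function(g) genus_frequency(m, tissue, g),
                            numeric(1))), 1)
  }
})

test_that("class composition rolls genera up through the taxonomy map", {
  iso <- monarda_records()
  taxmap <- read_taxonomy_map(endodiv_example("monarda_taxonomy.tsv"))
  cc <- class_composition(iso, taxmap)
  expect_equal(sum(cc), 1)
  expect_equal(unname(cc["Dothideomycetes"]), 7 / 28)
  expect_equal(unname(cc["Sordariomycetes"]), 14 / 28)
  expect_equal(unname(cc["Eurotiomycetes"]), 7 / 28)
  expect_error(class_composition(iso, taxmap[taxmap$genus != "Muscodor", ]),
               "Muscodor")
  one <- class_composition(iso[1, ], taxmap)
  expect_equal(unname(one), 1)
})

test_that("presence sets pick taxa with positive counts", {
  m <- monarda_matrix()
  expect_setequal(presence_set(m, "root"),
                  c("Alternaria carthami", "Cladosporium sp."))
  expect_length(presence_set(m, "flower"), 6)
  expect_error(presence_set(m, "stem"), "unknown tissue")
  m0 <- unclass(m); m0[, "root"] <- 0L
  class(m0) <- class(m)
  expect_length(presence_set(m0, "root"), 0)
})

test_that("column sums equal tissue record counts for simulated communities", {
  set.seed(7)
  for (i in 1:5) {
    comp <- list(leaf = stats::setNames(rep(1 / 6, 6), paste("Taxon", letters[1:6])),
                 flower = stats::setNames(c(0.5, 0.5), c("Taxon a", "Taxon z")))
    n <- c(leaf = sample(5:40, 1), flower = sample(5:40, 1))
    m <- build_abundance_matrix(simulate_community(comp, n))
    expect_equal(colSums(m)[c("leaf", "flower")], n)
  }
})
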