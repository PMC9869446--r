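# small handcrafted table with hand-checkable descriptives
toy_interactions <- function() {
  tibble::tibble(
    bee_species = c("a", "a", "a", "a", "b", "b", "c", "c", "c", "d"),
    bee_genus = "g1",
    sociality = c(rep("eusocial", 6), rep("solitary", 4)),
    proboscis_mm = c(rep(2, 4), rep(7, 2), rep(4, 3), 10),
    plant_species = paste0("p", 1:10),
    symmetry = c("radial", "radial", "bilateral", "bilateral",
                 "bilateral", "bilateral", "radial", "radial", "bilateral",
                 "bilateral"),
    corolla_mm = c(1, 2, 5, 5, 8, 8, 2, 2, 3, 12),
    round = 1L,
    plot = 1L
  )
}

test_that("interaction tables round-trip through CSV with schema checks", {
  tbl <- toy_interactions()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  back <- read_interactions(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))

  # missing mandatory columns are reported by name
  bad <- dplyr::select(tbl, -sociality, -symmetry)
  readr::write_csv(bad, path)
  expect_error(read_interactions(path), "sociality, symmetry")

  # an empty file with a header yields an empty table, silently
  readr::write_csv(tbl[0, ], path)
  expect_identical(nrow(read_interactions(path)), 0L)

  # intermediate sociality levels are dropped with a message
  mixed <- dplyr::mutate(tbl, sociality = replace(sociality, 1:2, "subsocial"))
  readr::write_csv(mixed, path)
  expect_message(got <- read_interactions(path), "dropped 2")
  expect_identical(nrow(got), 8L)

  # invalid traits are rejected
  neg <- dplyr::mutate(tbl, proboscis_mm = replace(proboscis_mm, 1, -1))
  readr::write_csv(neg, path)
  expect_error(read_interactions(path), "proboscis_mm")
})

test_that("complexity counts partition the visits", {
  tbl <- toy_interactions()
  cs <- complexity_counts(tbl, "symmetry")
  expect_identical(as.character(cs$class), c("radial", "bilateral"))
  expect_identical(cs$n, c(4L, 6L))
  expect_identical(sum(cs$n), nrow(tbl))

  cd <- complexity_counts(tbl, "depth")
  expect_identical(as.character(cd$class), c("shallow", "deep"))
  expect_identical(cd$n, c(5L, 5L))  # corolla of exactly 3 mm codes shallow

  one <- tbl[1, ]
  c1 <- complexity_counts(one, "symmetry")
  expect_identical(c1$n, c(1L, 0L))
})

test_that("depth coding boundary: 3 mm is shallow, just above is deep", {
  tbl <- toy_interactions()[1:2, ]
  tbl$corolla_mm <- c(3, 3 + 1e-9)
  coded <- code_complexity(tbl)
  expect_identical(coded$is_deep, c(FALSE, TRUE))
  # threshold is configurable
  coded5 <- code_complexity(tbl, deep_threshold = 1)
  expect_identical(coded5$is_deep, c(TRUE, TRUE))
})

test_that("per-species proportions and group summaries match hand computation", {
  tbl <- toy_interactions()
  sp <- per_species_proportions(tbl, "bilateral", summarise = FALSE)
  expect_equal(sp$proportion[match(c("a", "b", "c", "d"), sp$bee_species)],
               c(2 / 4, 1, 1 / 3, 1))

  gr <- per_species_proportions(tbl, "bilateral")
  # eusocial: species a (0.5) and b (1.0) -> mean 0.75, se = sd/sqrt(2)
  eu <- gr[gr$sociality == "eusocial", ]
  expect_identical(eu$n_species, 2L)
  expect_equal(eu$mean_proportion, 0.75)
  expect_equal(eu$se, sd(c(0.5, 1)) / sqrt(2))
  # solitary: c (1/3) and d (1)
  so <- gr[gr$sociality == "solitary", ]
  expect_equal(so$mean_proportion, mean(c(1 / 3, 1)))

  # a single-species group reports NA standard error
  single <- per_species_proportions(tbl[tbl$bee_species == "a", ], "bilateral")
  expect_true(is.na(single$se))

  # population-sd variant is smaller by sqrt((n-1)/n)
  grp <- per_species_proportions(tbl, "bilateral", sd_type = "population")
  expect_equal(grp$se[grp$sociality == "eusocial"],
               eu$se * sqrt(1 / 2))
})

test_that("group summaries are invariant to row order and k-fold duplication", {
  tbl <- toy_interactions()
  base <- per_species_proportions(tbl, "bilateral")
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(per_species_proportions(shuffled, "bilateral"), base)
  tripled <- dplyr::bind_rows(tbl, tbl, tbl)
  expect_equal(per_species_proportions(tripled, "bilateral"), base)
  # same for the deep-tube trait
  base_d <- per_species_proportions(tbl, "deep")
  expect_equal(per_species_proportions(tripled, "deep"), base_d)
})

test_that("corolla-depth group means support both weighting conventions", {
  tbl <- toy_interactions()
  both <- group_mean_corolla(tbl, "both")
  # species-level, eusocial: a = mean(1,2,5,5) = 3.25, b = 8 -> mean 5.625
  eu_sp <- both[both$sociality == "eusocial" & both$weighting == "species", ]
  expect_equal(eu_sp$mean_corolla_mm, mean(c(3.25, 8)))
  expect_equal(eu_sp$se, sd(c(3.25, 8)) / sqrt(2))
  # visit-level, eusocial: mean(1,2,5,5,8,8)
  eu_v <- both[both$sociality == "eusocial" & both$weighting == "visits", ]
  expect_equal(eu_v$mean_corolla_mm, mean(c(1, 2, 5, 5, 8, 8)))
  # the two conventions genuinely differ on unbalanced data
  expect_false(isTRUE(all.equal(eu_sp$mean_corolla_mm, eu_v$mean_corolla_mm)))
  # constant corolla: zero standard error
  const <- dplyr::mutate(tbl, corolla_mm = 4)
  cg <- group_mean_corolla(const, "species")
  expect_true(all(cg$mean_corolla_mm == 4))
  expect_true(all(cg$se[!is.na(cg$se)] == 0))
})

test_that("size-class shares sum to one within each flower class", {
  tbl <- toy_interactions()
  sz <- size_class_summary(tbl)
  for (cl in unique(sz$flower_class)) {
    expect_equal(sum(sz$share[sz$flower_class == cl]), 1)
  }
  # radial visits: proboscis 2,2,4,4 -> bins [0,3] share 0.5, (3,6] share 0.5
  rad <- sz[sz$flower_class == "radial", ]
  expect_equal(rad$share[as.character(rad$proboscis_bin) == "[0,3]"], 0.5)
  # single-bin table
  small <- tbl[tbl$proboscis_mm == 2, ]
  sz1 <- size_class_summary(small)
  expect_true(all(sz1$share[as.character(sz1$proboscis_bin) == "[0,3]"] == 1))
})

test_that("choice regression recovers a null on balanced deterministic data", {
  # response independent of predictors by construction: every species visits
  # one bilateral and one radial flower
  tbl <- tibble::tibble(
    bee_species = rep(c("a", "b", "c", "d"), each = 2),
    sociality = rep(c("eusocial", "solitary"), each = 4),
    proboscis_mm = rep(c(2, 9, 4, 6), each = 2),
    plant_species = "p",
    symmetry = rep(c("radial", "bilateral"), 4),
    corolla_mm = rep(c(1, 6), 4)
  )
  fit <- fit_choice_regression(tbl, "bilateral")
  expect_s3_class(fit, "choice_fit")
  expect_true(all(abs(tidy(fit)$estimate) < 1e-6))
  expect_false(fit$separation)
  expect_identical(glance(fit)$n_visits, 8L)

  # complete separation is flagged
  sep <- dplyr::mutate(tbl,
                       symmetry = ifelse(sociality == "eusocial",
                                         "bilateral", "radial"))
  expect_warning(fit2 <- fit_choice_regression(sep, "bilateral"), "separation")
  expect_true(fit2$separation)
})

test_that("descriptive report assembles and writes every table", {
  tbl <- toy_interactions()
  dir <- withr::local_tempdir()
  rep <- interaction_descriptives(tbl, out_dir = dir)
  expect_named(rep, c("counts_symmetry", "counts_depth",
                      "bilateral_by_sociality", "deep_by_sociality",
                      "corolla_by_sociality", "size_classes"))
  files <- list.files(dir, pattern = "^descriptives_")
  expect_identical(length(files), 6L)
})
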