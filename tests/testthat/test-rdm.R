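test_that("the 12-entry index pairs every stimulus with both sections", {
  ent <- rsa_entries()
  expect_equal(nrow(ent), 12)
  expect_equal(nrow(dplyr::distinct(ent[c("stimulus", "section")])), 12)
  expect_equal(sum(ent$group == "face"), 4)
  expect_equal(nrow(entry_pairs()), 66)
})

test_that("stimulus recognizer model: all pairs high except cross-section repeats", {
  m <- build_model_rdm("stimulus_recognizer")
  up <- upper.tri(m$values)
  expect_equal(sum(m$mask[up]), 66)
  expect_equal(sum(m$values[up & m$mask] == 0), 6)
  expect_equal(sum(m$values[up & m$mask] == 1), 60)
  expect_true(all(m$values[m$mask] %in% c(0, 1)))
})

test_that("category-vs-nonsense model masks the repeats and the other category", {
  m <- build_model_rdm("category_vs_nonsense", "face")
  up <- upper.tri(m$values)
  valid <- up & m$mask
  expect_equal(sum(valid), 24)                 # 28 cells among 8 entries - 4 masked
  expect_equal(sum(m$values[valid] == 1), 16)  # 4 face x 4 nonsense entries
  expect_equal(sum(m$values[valid] == 0), 8)
  ent <- rsa_entries()
  tool_entries <- ent$entry[ent$group == "tool"]
  expect_false(any(m$mask[tool_entries, ]))
  # symmetric story for tools
  mt <- build_model_rdm("category_vs_nonsense", "tool")
  expect_equal(sum(mt$mask[up]), 24)
  expect_false(any(mt$mask[ent$entry[ent$group == "face"], ]))
})

test_that("one-vs-rest model keeps all entries and masks all 6 repeats", {
  m <- build_model_rdm("one_vs_rest", "face")
  up <- upper.tri(m$values)
  valid <- up & m$mask
  expect_equal(sum(valid), 60)
  expect_equal(sum(m$values[valid] == 1), 32)  # 4 face entries x 8 others
  expect_equal(sum(m$values[valid] == 0), 28)

  mm <- build_model_rdm("one_vs_rest", "meaningful")
  validm <- up & mm$mask
  expect_equal(sum(validm), 60)
  expect_equal(sum(mm$values[validm] == 1), 32) # 8 meaningful x 4 nonsense
  ent <- rsa_entries()
  ft <- mm$values[ent$entry[ent$group == "face"], ent$entry[ent$group == "tool"]]
  expect_true(all(ft == 0))                     # face-tool is within-group

  # type 2 entry support is a strict subset of type 3's
  m2 <- build_model_rdm("category_vs_nonsense", "face")
  expect_true(all(which(rowSums(m2$mask) > 0) %in% which(rowSums(m$mask) > 0)))
  expect_gt(sum(rowSums(m$mask) > 0), sum(rowSums(m2$mask) > 0))
})

test_that("model construction rejects bad specs", {
  expect_error(build_model_rdm("category_vs_nonsense"),
               class = "megrsa_invalid_argument")
  expect_error(build_model_rdm("one_vs_rest", "nonsense"),
               class = "megrsa_invalid_argument")
  expect_error(build_model_rdm("stimulus_recognizer", "face"),
               class = "megrsa_invalid_argument")
})

test_that("empirical RDMs mirror the pair accuracies symmetrically", {
  comp <- null_components(n_regions = 1, n_trials = 50)
  dec <- decode_conditions(comp, n_randomizations = 5, min_trials = 50, seed = 3)
  rdm <- build_empirical_rdm(dec, region = 1, time_bin = 40)
  expect_identical(rdm$values, t(rdm$values))
  expect_identical(rdm$mask, t(rdm$mask))
  expect_equal(sum(rdm$mask[upper.tri(rdm$mask)]), 66)
  expect_false(any(diag(rdm$mask)))
  pr <- dec$pairs
  i <- 25
  expect_equal(rdm$values[pr$a[i], pr$b[i]], dec$accuracy[1, 40, i])
})

test_that("an excluded condition leaves 11 usable entries and 55 cells", {
  trials <- matrix(60L, 6, 2); trials[4, 1] <- 10L
  cfg <- tiny_config(n_subjects = 1, n_regions = 1, n_trials = trials)
  parc <- build_synthetic_parcellation(1, 5, seed = cfg$seed)
  comp <- extract_region_components(simulate_subject(cfg, 1, parc)$epochs, parc)
  dec <- decode_conditions(comp, n_randomizations = 4, min_trials = 50, seed = 1)
  rdm <- build_empirical_rdm(dec, 1, 10)
  expect_equal(sum(rdm$mask[upper.tri(rdm$mask)]), choose(11, 2))
})

test_that("RDM correlation matches a brute-force rank oracle", {
  # hand example: model (0,0,1,1) vs empirical (0.52, 0.55, 0.71, 0.66)
  expect_equal(spearman_oracle(c(0.52, 0.55, 0.71, 0.66), c(0, 0, 1, 1)),
               0.8944272, tolerance = 1e-6)

  m <- build_model_rdm("one_vs_rest", "face")
  up <- upper.tri(m$values)
  joint <- up & m$mask
  withr::with_seed(8, {
    emp_vals <- matrix(0, 12, 12)
    emp_vals[up] <- runif(66, 0.4, 0.9)
    emp_vals <- emp_vals + t(emp_vals)
  })
  emp <- new_rdm(emp_vals, matrix(TRUE, 12, 12))
  expect_equal(correlate_rdms(emp, m),
               spearman_oracle(emp_vals[joint], m$values[joint]))
})

test_that("RDM correlation hits the exact bounds and handles degeneracy", {
  m <- build_model_rdm("stimulus_recognizer")
  same <- new_rdm(m$values, m$mask)
  expect_equal(correlate_rdms(same, m), 1)
  flipped <- new_rdm(1 - m$values, m$mask)
  expect_equal(correlate_rdms(flipped, m), -1)

  # constant empirical or too few joint cells -> NA, not zero
  const <- new_rdm(matrix(0.5, 12, 12), m$mask)
  expect_true(is.na(correlate_rdms(const, m)))
  tiny_mask <- matrix(FALSE, 12, 12)
  tiny_mask[1, 2] <- tiny_mask[2, 1] <- TRUE
  expect_true(is.na(correlate_rdms(new_rdm(matrix(0.5, 12, 12), tiny_mask), m)))
})

test_that("rank correlation is invariant to monotone transforms", {
  m <- build_model_rdm("one_vs_rest", "tool")
  withr::with_seed(12, {
    vals <- matrix(0, 12, 12)
    up <- upper.tri(vals)
    vals[up] <- runif(66, 0.3, 0.95)
    vals <- vals + t(vals)
  })
  emp1 <- new_rdm(vals, matrix(TRUE, 12, 12))
  emp2 <- new_rdm(exp(3 * vals), matrix(TRUE, 12, 12))
  expect_equal(correlate_rdms(emp1, m), correlate_rdms(emp2, m))
})

test_that("Fisher transform is atanh with clipping at unity", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- c(0.1, 0.4, 0.77)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z(1), atanh(1 - 1e-6))
  expect_true(is.finite(fisher_z(-1)))
  expect_true(is.na(fisher_z(NA)))
})
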