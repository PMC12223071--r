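test_that("noise-free phantom is piecewise constant at the configured levels", {
  s <- generate_phantom(phantom_spec(noise_sigma = 0, tumor_present = FALSE,
                                     seed = 1))
  expect_setequal(unique(as.vector(s$image)), c(0.05, 0.45, 0.95))
  expect_equal(s$label, "no-tumor")
  s2 <- generate_phantom(phantom_spec(noise_sigma = 0, seed = 1))
  expect_setequal(unique(as.vector(s2$image)), c(0.05, 0.45, 0.75, 0.95))
})

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(phantom_spec(seed = 33))
  b <- generate_phantom(phantom_spec(seed = 33))
  expect_identical(a$image, b$image)
  expect_identical(a$tumor_mask, b$tumor_mask)
  c <- generate_phantom(phantom_spec(seed = 34))
  expect_false(identical(a$image, c$image))
})

test_that("tumor blob area tracks the nominal radius", {
  for (seed in 1:8) {
    s <- generate_phantom(phantom_spec(tumor_radius = 6, seed = seed))
    area <- sum(s$tumor_mask)
    expect_gt(area, 0.5 * pi * 36)
    expect_lt(area, 1.5 * pi * 36)
  }
})

test_that("tumor geometry invariants hold: inside brain, single component", {
  for (seed in 1:10) {
    s <- generate_phantom(phantom_spec(seed = seed))
    expect_true(all(s$brain_mask[s$tumor_mask]))
    lab <- EBImage::bwlabel(EBImage::Image(s$tumor_mask * 1))
    expect_equal(max(lab), 1)
  }
})

test_that("oversized tumors are rejected as geometry errors", {
  expect_error(generate_phantom(phantom_spec(tumor_radius = 30)),
               "geometry")
})

test_that("generate_dataset forces the tumor count", {
  d <- generate_dataset(100, 0.5, spec32(), seed = 5)
  expect_length(d, 100)
  expect_equal(sum(vapply(d, `[[`, "", "label") == "tumor"), 50)
  d0 <- generate_dataset(20, 0, spec32(), seed = 5)
  expect_true(all(vapply(d0, `[[`, "", "label") == "no-tumor"))
  d2 <- generate_dataset(40, 0.6, spec32(), seed = 5)
  expect_equal(sum(vapply(d2, `[[`, "", "label") == "tumor"), 24)
  expect_error(generate_dataset(0, 0.5), "positive")
})

test_that("same master seed reproduces the dataset byte for byte", {
  d1 <- generate_dataset(12, 0.5, spec32(), seed = 9)
  d2 <- generate_dataset(12, 0.5, spec32(), seed = 9)
  expect_identical(lapply(d1, `[[`, "image"), lapply(d2, `[[`, "image"))
})

test_that("pseudo-modality remap preserves masks and honors monotonicity", {
  s <- generate_phantom(phantom_spec(seed = 2))
  idn <- make_pseudo_modality(s, lookup = seq(0, 1, length.out = 9),
                              blur_sigma = 0)
  expect_equal(idn$image, s$image, tolerance = 1e-12)
  expect_equal(idn$modality, "pseudo-mri")
  inv <- make_pseudo_modality(s, lookup = seq(1, 0, length.out = 9),
                              blur_sigma = 0)
  # intensity order inverted: skull (brightest) becomes darkest
  skull <- s$image > 0.9
  expect_gt(mean(s$image[skull]), mean(s$image[s$brain_mask]))
  expect_lt(mean(inv$image[skull]), mean(inv$image[s$brain_mask]))
  pm <- make_pseudo_modality(s)
  expect_identical(pm$tumor_mask, s$tumor_mask)
  expect_identical(pm$brain_mask, s$brain_mask)
  expect_identical(pm$label, s$label)
  expect_error(make_pseudo_modality(s, lookup = c(0, 0.8, 0.5, 1)),
               "monotone")
  expect_error(make_pseudo_modality(pm), "modality")
})

test_that("client partition honors the heterogeneous cohort profiles", {
  ds <- generate_dataset(300, 0.5, spec32(), seed = 7,
                         type_mix = cohort_type_mix)
  ps <- lapply(ds, make_pseudo_modality)
  parts <- partition_clients(c(ds, ps), default_client_profiles(scale = 0.1),
                             seed = 1)
  expect_length(parts, 5)
  # the skewed client holds only glioma-like tumor scans
  c3 <- parts[["client-3"]]
  types <- vapply(c3, `[[`, "", "tumor_type")
  labels <- vapply(c3, `[[`, "", "label")
  expect_true(all(types[labels == "tumor"] == "glioma-like"))
  # true partition: pairwise disjoint
  ids <- lapply(parts, function(cl) vapply(cl, `[[`, "", "id"))
  expect_equal(length(unlist(ids)), length(unique(unlist(ids))))
  # client tags applied
  expect_true(all(vapply(c3, `[[`, "", "client_id") == "client-3"))
})

realized_mix <- function(ds) {
  types <- vapply(ds, `[[`, "", "tumor_type")
  tab <- table(factor(types[vapply(ds, `[[`, "", "label") == "tumor"],
                      levels = names(cohort_type_mix)))
  as.numeric(tab) / sum(tab)
}

test_that("a single all-consuming profile returns the whole dataset", {
  ds <- generate_dataset(40, 0.5, spec32(), seed = 3)
  mix <- stats::setNames(realized_mix(ds), names(cohort_type_mix))
  pr <- client_profile("solo", n_ct = 40, type_mix = mix)
  parts <- partition_clients(ds, list(pr), seed = 1)
  expect_setequal(vapply(parts$solo, `[[`, "", "id"),
                  vapply(ds, `[[`, "", "id"))
})

test_that("60 + 40 split of 100 scans is disjoint with full union", {
  ds <- generate_dataset(100, 0.5, spec32(), seed = 4)
  types <- vapply(ds, `[[`, "", "tumor_type")
  counts <- table(factor(types[vapply(ds, `[[`, "", "label") == "tumor"],
                         levels = names(cohort_type_mix)))
  # integer-exact per-type demands so the two clients drain the pools fully
  ca <- phantomfed:::apportion(30, as.numeric(counts) / 50)
  cb <- as.numeric(counts) - ca
  prs <- list(
    client_profile("a", 60,
                   type_mix = stats::setNames(ca / 30,
                                              names(cohort_type_mix))),
    client_profile("b", 40,
                   type_mix = stats::setNames(cb / 20,
                                              names(cohort_type_mix))))
  parts <- partition_clients(ds, prs, seed = 2)
  ia <- vapply(parts$a, `[[`, "", "id")
  ib <- vapply(parts$b, `[[`, "", "id")
  expect_length(intersect(ia, ib), 0)
  expect_setequal(c(ia, ib), vapply(ds, `[[`, "", "id"))
})

test_that("infeasible client mixes report the shortage explicitly", {
  ds <- generate_dataset(10, 0.5, spec32(), seed = 4)
  expect_error(partition_clients(ds, list(client_profile("big", 50)), 1),
               "infeasible")
})

test_that("dataset export writes PNGs and a readable manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(4, 0.5, spec32(), seed = 8)
  m <- write_dataset(ds, dir)
  expect_true(all(file.exists(m$path)))
  back <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                            sep = "\t")
  expect_equal(nrow(back), 4)
  img <- png::readPNG(m$path[1])
  expect_equal(dim(img), c(32, 32))
  expect_equal(max(abs(img - ds[[1]]$image)), 0, tolerance = 1 / 255)
})
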