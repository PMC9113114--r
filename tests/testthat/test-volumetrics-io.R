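make_volume_csv <- function(path, unit = 1, rename = NULL, drop = NULL,
                            extra = NULL, n = 4) {
  co <- generate_cohort(cohort_config(n_td = n, n_asd = 0), seed = 101)
  v <- generate_volume_table(co, seed = 101)
  v[, cerebellar_rois()] <- v[, cerebellar_rois()] * unit
  if (!is.null(rename)) names(v)[match(names(rename), names(v))] <- rename
  if (!is.null(drop)) v <- v[, setdiff(names(v), drop)]
  if (!is.null(extra)) v[[extra]] <- 1
  utils::write.csv(v, path, row.names = FALSE)
  v
}

test_that("mm3 tables are converted to cm3 on load", {
  path <- withr::local_tempfile(fileext = ".csv")
  v <- make_volume_csv(path, unit = 1000)
  out <- load_volume_table(path, unit = "mm3")
  expect_equal(out$vermis_VI_VII, v$vermis_VI_VII / 1000)
  # 1654 mm3 -> 1.654 cm3
  out$vermis_VI_VII <- NULL
  v2 <- utils::read.csv(path)
  v2$vermis_VI_VII <- 1654
  utils::write.csv(v2, path, row.names = FALSE)
  expect_equal(load_volume_table(path, unit = "mm3")$vermis_VI_VII,
               rep(1.654, nrow(v2)))
})

test_that("a missing ROI column is a named error", {
  path <- withr::local_tempfile(fileext = ".csv")
  make_volume_csv(path, drop = "right_lobule_X")
  expect_error(load_volume_table(path), "right lobule X")
})

test_that("segmentation-tool aliases map onto the canonical schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  make_volume_csv(path, rename = c(white_matter = "Corpus Medullare",
                                   vermis_VI_VII = "Vermis VI-VII",
                                   left_crus_II_VIIB = "Left Crus II"))
  out <- load_volume_table(path)
  expect_true(all(cerebellar_rois() %in% names(out)))
})

test_that("unknown columns are reported, never silently dropped", {
  path <- withr::local_tempfile(fileext = ".csv")
  make_volume_csv(path, extra = "brainstem")
  expect_warning(out <- load_volume_table(path), "brainstem")
  expect_identical(attr(out, "unknown_columns"), "brainstem")
})

test_that("non-positive volumes are QC-flagged by participant", {
  path <- withr::local_tempfile(fileext = ".csv")
  v <- make_volume_csv(path)
  v$left_crus_I[2] <- -1
  utils::write.csv(v, path, row.names = FALSE)
  expect_warning(out <- load_volume_table(path), v$participant_id[2])
  expect_equal(attr(out, "qc")$participant_id, v$participant_id[2])
})

test_that("generator output round-trips through save and load", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- generate_cohort(cohort_config(n_td = 6, n_asd = 0), seed = 7)
  v <- generate_volume_table(co, seed = 7)
  write_volume_table(v, path)
  out <- load_volume_table(path)
  expect_equal(out, v, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the total composite conserves the sum of its parts exactly", {
  ones <- data.frame(participant_id = "P1")
  for (r in cerebellar_rois()) ones[[r]] <- 1
  expect_equal(derive_composites(ones)$total_cerebellum, 18)
  co <- generate_cohort(cohort_config(n_td = 5, n_asd = 0), seed = 8)
  v <- generate_volume_table(co, seed = 8)
  tot <- derive_composites(v)
  expect_equal(tot$total_cerebellum, rowSums(v[, cerebellar_rois()]))
  v2 <- v
  v2$left_crus_I <- 0
  expect_equal(tot$total_cerebellum - derive_composites(v2)$total_cerebellum,
               v$left_crus_I)
  # zero-noise TD table totals the sum of the configured baselines
  v0 <- generate_volume_table(co, volume_effects_config(noise_scale = 0),
                              seed = 1)
  par <- default_volume_params()
  expect_equal(unique(derive_composites(v0)$total_cerebellum),
               sum(par$mean[par$group == "TD"]))
})
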