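# Reading, validating and bundling composition, activity and z-scale tables.

test_that("bundled dataset reproduces the printed composition panel", {
  ds <- bundled_dataset()
  comp <- ds$composition
  expect_s3_class(comp, "composition_matrix")
  expect_identical(dim(unclass(comp)), c(16L, 18L))
  expect_identical(colnames(comp), aa_labels)
  # spot values straight from the published table
  expect_equal(comp["1", "ASX"], 11.39)
  expect_equal(comp["1", "TRP"], 1.23)
  expect_equal(comp["16", "ARG"], 30.18)
  expect_equal(comp["7", "TRP"], 0.00)
  expect_equal(sum(comp["1", ]), 100.00, tolerance = 1e-12)
  expect_true(all(rowSums(comp) >= 95 & rowSums(comp) <= 105))
  # published group-sum reference block attached
  expect_equal(ds$groups_ref["9", "AAA"], 16.62)
  expect_equal(ds$groups_ref["16", "PCAA"], 51.19)
  expect_length(ds$activities, 0L)
})

test_that("composition reader round-trips and rejects malformed tables", {
  path <- write_tiny_composition_csv()
  comp <- read_composition(path)
  expect_equal(unclass(comp), unclass(tiny_composition()),
               ignore_attr = TRUE)
  expect_identical(rownames(comp), paste0("T", 1:4))

  # tab-delimited accepted via the sep flag
  tpath <- write_tiny_composition_csv(tempfile(fileext = ".tsv"), sep = "\t")
  expect_equal(unclass(read_composition(tpath, sep = "\t")),
               unclass(comp), ignore_attr = TRUE)

  # missing amino-acid column is named in the error
  expect_error(read_composition(write_tiny_composition_csv(drop_col = "TRP")),
               "TRP")
  # non-numeric cell reported with position
  bad <- readLines(path)
  bad[3] <- sub("12", "oops", bad[3])
  bpath <- tempfile(fileext = ".csv")
  writeLines(bad, bpath)
  expect_error(read_composition(bpath), "oops")
})

test_that("row-sum check warns by default and is promotable to an error", {
  vals <- unclass(tiny_composition())
  vals[2, ] <- vals[2, ] / 2  # sums to 50
  expect_warning(composition_matrix(vals), "\\[95, 105\\]")
  expect_warning(composition_matrix(vals), "T2")
  expect_error(composition_matrix(vals, row_sum_action = "error"), "T2")
  expect_silent(composition_matrix(vals, row_sum_action = "none"))
  # negative and missing values always rejected
  vals2 <- unclass(tiny_composition()); vals2[1, 1] <- -1
  expect_error(composition_matrix(vals2), "non-negative")
  vals3 <- unclass(tiny_composition()); vals3[1, 1] <- NA
  expect_error(composition_matrix(vals3), "missing")
})

test_that("z-scale pooling averages the amide/acid pairs", {
  z <- read_zscales()
  expect_identical(rownames(z), aa_labels)
  # ASX = mean(Asn, Asp), GLX = mean(Gln, Glu), per source records
  expect_equal(unlist(z["ASX", ]), c(z1 = 3.43, z2 = 1.29, z3 = 1.60))
  expect_equal(unlist(z["GLX", ]), c(z1 = 2.63, z2 = 0.46, z3 = -0.605))
})

test_that("z-scale ordering invariants are enforced", {
  src <- read.csv(system.file("extdata", "hellberg_zscales.csv",
                              package = "aapls"), comment.char = "#")
  # push Cys z3 below Pro: breaks the electronic-property ordering
  bad <- src
  bad$z3[bad$aa == "CYS"] <- 1.0
  path <- tempfile(fileext = ".csv")
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_zscales(path), "Cys > Pro > Asx > His > Trp")

  # duplicate row for GLY
  dup <- rbind(src, src[src$aa == "GLY", ])
  path2 <- tempfile(fileext = ".csv")
  write.csv(dup, path2, row.names = FALSE)
  expect_error(read_zscales(path2), "duplicate.*GLY")

  # missing amino acid
  path3 <- tempfile(fileext = ".csv")
  write.csv(src[src$aa != "MET", ], path3, row.names = FALSE)
  expect_error(read_zscales(path3), "MET")
})

test_that("activity tables enforce subset and completeness rules", {
  comp <- tiny_composition()
  act <- activity_table(c("T1", "T2", "T3"), c(50, 60, 70), "dpph")
  ds <- aa_dataset(comp, list(dpph = act))
  expect_named(ds$activities, "dpph")
  # a sample id outside the composition panel is rejected
  stray <- activity_table(c("T1", "T9"), c(1, 2), "dpph")
  expect_error(aa_dataset(comp, list(dpph = stray)), "T9")
  # missing values within the declared subset are rejected
  expect_error(activity_table(c("T1", "T2"), c(1, NA), "dpph"), "missing")
  expect_error(activity_table(c("T1", "T1"), c(1, 2), "dpph"), "duplicate")
})

test_that("activity files load per-assay subsets (the loader hook)", {
  ds <- bundled_dataset()
  path <- tempfile(fileext = ".csv")
  df <- data.frame(sample_id = 1:16,
                   dpph = round(runif(16, 20, 80), 2),
                   frap = round(runif(16, 0.1, 1.2), 3),
                   h2o2 = c(round(runif(11, 10, 70), 2), rep(NA, 5)))
  write.csv(df, path, row.names = FALSE, na = "")
  ds2 <- with_activities(ds, path)
  expect_named(ds2$activities, c("dpph", "frap", "h2o2"))
  expect_equal(nrow(ds2$activities$h2o2), 11L)
  expect_equal(nrow(ds2$activities$dpph), 16L)
  expect_identical(attr(ds2$activities$frap, "units"), "absorbance_700nm")
})

test_that("reports serialize losslessly and refuse to write empty shells", {
  rep <- structure(list(activity = "dpph", n = 16L, x_set = "all", a = 1L,
                        r2 = 0.40723456789012345, q2cv = 0.3271234567890123,
                        perm_r2_intercept = 0.2411111111111111,
                        perm_q2_intercept = -0.0961234512345,
                        valid = TRUE),
                   class = "validation_report")
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  for (f in c("r2", "q2cv", "perm_r2_intercept", "perm_q2_intercept"))
    expect_identical(back[[f]], rep[[f]])
  expect_identical(back$n, 16L)
  expect_true(back$valid)
  # csv rendering carries the same columns
  cpath <- tempfile(fileext = ".csv")
  write_report(rep, cpath, format = "csv")
  tab <- read.csv(cpath)
  expect_true(all(c("n", "x_set", "a", "r2", "q2cv", "perm_r2_intercept",
                    "perm_q2_intercept", "valid") %in% names(tab)))
  # an unpopulated report is an error, never an empty file
  empty <- structure(list(), class = "validation_report")
  expect_error(write_report(empty, tempfile()), "not fully populated")
})
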