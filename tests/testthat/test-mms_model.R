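test_that("bundled taxonomy has 64 uniquely coded KPIs split 12/13/33/6", {
  tax <- mms_taxonomy()
  expect_equal(nrow(tax), 64L)
  expect_false(anyDuplicated(tax$code) > 0)
  expect_equal(as.vector(table(tax$dataset)[c("AVA", "PLA", "WOF", "USE")]),
               c(12L, 13L, 33L, 6L))
  # code prefixes match dataset membership
  expect_equal(unname(c(AVA = "A", PLA = "P", WOF = "W", USE = "U")[tax$dataset]),
               substr(tax$code, 1L, 1L))
  # unit conventions: inputs per 100,000; length of stay in days;
  # re-admission per 100 discharges; other utilisation per 1,000
  expect_true(all(tax$unit[tax$dataset != "USE"] == "per 100,000 inhabitants"))
  expect_equal(tax$unit[tax$code == "U2"], "days")
  expect_equal(tax$unit[tax$code == "U3"], "per 100 discharges")
  expect_true(all(tax$unit[tax$code %in% c("U1", "U4", "U5", "U6")] ==
                  "per 1,000 inhabitants"))
})

test_that("region registry expands to 106 labelled areas", {
  reg <- region_registry()
  expect_equal(sum(reg$n_areas), 106L)
  expect_true(sum(reg$population) > 9e6)
  ar <- area_registry()
  expect_equal(nrow(ar), 106L)
  expect_false(anyDuplicated(ar$label) > 0)
  expect_equal(substr(ar$label, 1L, 1L),
               reg$prefix[match(ar$region, reg$region)])
})

test_that("CSV load/write round trip is value- and byte-identical", {
  sys <- generate_system(paper_like_config(seed = 3))
  d <- withr::local_tempdir()
  csv <- file.path(d, "mms.csv"); meta <- file.path(d, "meta.json")
  write_mms(sys$tables, csv)
  write_mms_metadata(meta)
  tabs <- load_mms(csv, meta)
  expect_equal(names(tabs), c("AVA", "PLA", "WOF", "USE"))
  expect_equal(vapply(tabs, function(t) ncol(t$values), 0L),
               c(AVA = 12L, PLA = 13L, WOF = 33L, USE = 6L))
  expect_equal(nrow(tabs$USE$values), 106L)
  for (ds in names(tabs)) {
    expect_equal(tabs[[ds]]$values, sys$tables[[ds]]$values)
  }
  csv2 <- file.path(d, "mms2.csv")
  write_mms(tabs, csv2)
  expect_identical(readLines(csv2), readLines(csv))
})

test_that("schema violations are rejected at load", {
  sys <- generate_system(paper_like_config(seed = 3))
  d <- withr::local_tempdir()
  csv <- file.path(d, "mms.csv"); meta <- file.path(d, "meta.json")
  write_mms(sys$tables, csv)
  write_mms_metadata(meta)
  lines <- readLines(csv)
  # unknown indicator column
  bad <- sub("^area,region,A1,", "area,region,X9,", lines)
  writeLines(bad, file.path(d, "bad1.csv"))
  expect_error(load_mms(file.path(d, "bad1.csv"), meta), "X9")
  # duplicate area label
  writeLines(c(lines, lines[2L]), file.path(d, "bad2.csv"))
  expect_error(load_mms(file.path(d, "bad2.csv"), meta), "duplicate")
  # negative value
  bad3 <- lines
  bad3[2L] <- sub("^(([^,]*,){2})[^,]*", "\\1-1.0", bad3[2L])
  writeLines(bad3, file.path(d, "bad3.csv"))
  expect_error(load_mms(file.path(d, "bad3.csv"), meta), "negative")
})

test_that("validation reports cardinalities and the W3 consistency rule", {
  sys <- generate_system(paper_like_config(seed = 5))
  rep <- validate_mms(sys$tables)
  expect_true(rep$ok)
  expect_equal(rep$n_indicators, 64L)
  card <- rep$checks[rep$checks$check == "cardinality", ]
  expect_true(all(card$status == "pass"))
  # break the W3 = W1 + W2 + other rule -> warning-level finding
  tabs <- sys$tables
  tabs$WOF$values[1L, "W1"] <- 3; tabs$WOF$values[1L, "W2"] <- 4
  tabs$WOF$values[1L, "W3"] <- 5
  rep2 <- validate_mms(tabs)
  w3 <- rep2$checks[rep2$checks$check == "W3 >= W1 + W2", ]
  expect_equal(w3$status, "warn")
  expect_match(w3$detail, tabs$WOF$areas$label[1L])
  expect_true(rep2$ok)  # warnings are not failures
})

test_that("min-max normalization maps ranges to [0,1] and flags constants", {
  v <- cbind(U1 = c(2, 4, 6), U2 = c(5, 5, 5), U3 = c(1, NA, 3),
             U4 = c(1, 2, 3), U5 = c(4, 5, 6), U6 = c(7, 8, 9))
  tab <- make_use_table(v)
  nm <- normalize_mms(tab)
  expect_equal(unname(nm$table$values[, "U1"]), c(0, 0.5, 1))
  expect_equal(unname(nm$table$values[, "U2"]), c(0.5, 0.5, 0.5))
  expect_true(nm$scaler$degenerate[nm$scaler$code == "U2"])
  expect_true(is.na(nm$table$values[2L, "U3"]))
  back <- denormalize_mms(nm$table$values, nm$scaler)
  expect_equal(back, tab$values, tolerance = 1e-12)
})

test_that("normalize/denormalize round trip is the identity on random tables", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:12, 1L)
    v <- matrix(rlnorm(n * 6, 1, 1), nrow = n)
    v[sample(length(v), n)] <- NA  # sprinkle missing values
    if (any(colSums(!is.na(v)) == 0L)) next
    tab <- make_use_table(v)
    nm <- normalize_mms(tab)
    back <- denormalize_mms(nm$table$values, nm$scaler)
    keep <- !nm$scaler$degenerate
    expect_equal(back[, keep], tab$values[, keep], tolerance = 1e-9)
  }
})

test_that("denormalization inverts the published length-of-stay range", {
  v <- cbind(U1 = c(1, 2), U2 = c(11.89, 34.23), U3 = c(0, 1),
             U4 = c(1, 2), U5 = c(1, 2), U6 = c(1, 2))
  nm <- normalize_mms(make_use_table(v))
  expect_equal(denormalize_mms(c(U2 = 0.5), nm$scaler)[["U2"]], 23.06)
  expect_equal(denormalize_mms(c(U2 = 0), nm$scaler)[["U2"]], 11.89)
  expect_equal(denormalize_mms(c(U2 = 1), nm$scaler)[["U2"]], 34.23)
  expect_error(denormalize_mms(c(Z9 = 0.5), nm$scaler), "absent")
})
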