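test_that("shipped constants file loads and carries the published values", {
  db <- load_database(pdma_constants_path())
  expect_s3_class(db, "equilibrium_database")
  ## the Zn-PDMA formation constant on its published conditional scale
  expect_equal(cond_at(db, "ZnPdma", 0.15), 11.48, tolerance = 1e-9)
  expect_equal(cond_at(db, "Fe3Pdma", 0.15), 17.37, tolerance = 1e-9)
  ## hydroxo complex is the log-additive sum of the printed steps
  expect_equal(cond_at(db, "ZnPdmaOH", 0.15), 11.48 - 9.69, tolerance = 1e-9)
  ## published stepwise numbers appear verbatim in the file
  txt <- paste(readLines(pdma_constants_path()), collapse = "\n")
  for (v in c("11.48", "17.37", "17.29", "-9.69", "10.32", "8.08", "2.66",
              "9.26", "4.885", "9.91", "-7.42"))
    expect_true(grepl(v, txt, fixed = TRUE), label = paste("contains", v))
})

test_that("divalent-metal stabilities follow the Irving-Williams ordering", {
  k <- vapply(c("Mn", "Fe2", "Co", "Zn", "Ni", "Cu"),
              function(m) cond_at(DB, paste0(m, "Pdma"), 0.15), numeric(1))
  expect_true(all(diff(k) >= 0))
  expect_lt(k[["Mn"]], k[["Fe2"]])
  expect_lt(k[["Ni"]], k[["Cu"]])
})

test_that("database validation rejects malformed rows", {
  tmp <- tempfile(fileext = ".csv")
  db <- pdma_database()
  write_database(db, tmp)
  lines <- readLines(tmp)
  i <- grep("^\"ZnPdma\",", lines)[1]
  expect_false(is.na(i))
  bad <- lines
  bad[i] <- sub(",-1,\"aqueous\"", ",-2,\"aqueous\"", bad[i], fixed = TRUE)
  writeLines(bad, tmp)
  expect_error(load_database(tmp), "charge imbalance")

  bad2 <- lines
  bad2[i] <- sub("Zn:1,Pdma:1", "Zq:1,Pdma:1", bad2[i], fixed = TRUE)
  writeLines(bad2, tmp)
  expect_error(load_database(tmp), "undeclared")
})

test_that("write -> load is the identity on the numeric payload", {
  tmp <- tempfile(fileext = ".csv")
  write_database(DB, tmp)
  db2 <- load_database(tmp)
  m <- match(DB$species$species, db2$species$species)
  expect_false(anyNA(m))
  expect_equal(db2$species$log_beta0[m], DB$species$log_beta0,
               tolerance = 1e-9)
  expect_identical(db2$species$charge[m], DB$species$charge)
})

test_that("the low-pH protonation steps are optional", {
  db <- pdma_database(include_low_pH = FALSE)
  expect_false(any(c("H4Pdma", "H5Pdma") %in% db$species$species))
  expect_true(all(c("H4Pdma", "H5Pdma") %in% DB$species$species))
})
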