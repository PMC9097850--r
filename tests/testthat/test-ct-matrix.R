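test_that("wide reader round-trips a full study and keeps dimensions", {
  m <- study_fixture()
  expect_equal(dim(m$ct), c(192L, 6L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(m, path)
  m2 <- read_ct_table(path)
  expect_equal(ct_genes(m2), ct_genes(m))
  expect_equal(m2$samples, m$samples)
  expect_equal(m2$ct, m$ct, tolerance = 1e-12)
})

test_that("metadata tokens are a closed, case-sensitive vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,condition,time_point,region,Gapdh,Actb",
               "s1,sham,12h,CX,20.1,18.2",
               "s2,tMCAO,12h,CX,20.3,18.0"), path)
  expect_error(read_ct_table(path), "sham")
  expect_error(read_ct_table(path), "SHAM, tMCAO")
  # an alias map recovers nonstandard tokens
  m <- read_ct_table(path, aliases = c(sham = "SHAM"))
  expect_equal(m$samples$condition, c("SHAM", "tMCAO"))
})

test_that("missing, duplicated and malformed cells are handled explicitly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,condition,time_point,region,Gapdh,Actb",
               "s1,SHAM,12h,CX,NA,18.2",
               "s2,SHAM,12h,CX,20.3,18.0",
               "s3,tMCAO,12h,CX,19.9,17.5"), path)
  m <- read_ct_table(path)
  expect_true(is.na(m$ct["s1", "Gapdh"]))
  expect_false(anyNA(m$ct[, "Actb"]))

  writeLines(c("sample_id,condition,time_point,region,Gapdh",
               "s1,SHAM,12h,CX,20.1",
               "s1,SHAM,12h,CX,20.3"), path)
  expect_error(read_ct_table(path), "duplicate sample_id")

  writeLines(c("sample_id,condition,time_point,region,Gapdh",
               "s1,SHAM,12h,CX,20.1",
               "s2,SHAM,12h,CX,2a.3"), path)
  expect_error(read_ct_table(path), "row 2.*Gapdh")
})

test_that("long reader pivots to the same matrix as the wide reader", {
  m <- study_fixture()
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(m, wide)
  df <- utils::read.csv(wide, stringsAsFactors = FALSE)
  ldf <- do.call(rbind, lapply(ct_genes(m), function(g) {
    data.frame(sample_id = df$sample_id, condition = df$condition,
               time_point = df$time_point, region = df$region,
               gene = g, ct = df[[g]])
  }))
  utils::write.csv(ldf, long, row.names = FALSE)
  m2 <- read_ct_long(long)
  expect_equal(m2$ct[rownames(m$ct), ct_genes(m)], m$ct, tolerance = 1e-12)
})

test_that("blocks partition the study and respect the design", {
  m <- study_fixture()
  seen <- character(0)
  for (r in rg_regions) {
    for (tp in rg_time_points) {
      b <- slice_block(m, r, tp)
      expect_equal(nrow(b$ct), 16L)
      expect_equal(unname(table(attr(b, "group_labels"))), c(8L, 8L),
                   ignore_attr = TRUE)
      seen <- c(seen, b$samples$sample_id)
    }
  }
  expect_setequal(seen, m$samples$sample_id)
  expect_equal(length(seen), nrow(m$ct))

  expect_error(slice_block(m, "CX", "5d"), "time_point")
  b <- slice_block(m, "CX", "12h", composition = "tmcao_only")
  expect_equal(nrow(b$ct), 8L)
  expect_true(all(b$samples$condition == "tMCAO"))
})

test_that("a depleted group stays a valid block", {
  m <- study_fixture()
  b <- slice_block(m, "CX", "12h")
  drop_id <- b$samples$sample_id[b$samples$condition == "tMCAO"][1]
  keep <- b$samples$sample_id != drop_id
  b2 <- make_block(b$ct[keep, ], condition = b$samples$condition[keep])
  expect_equal(unname(sort(table(attr(b2, "group_labels")))), c(7L, 8L),
               ignore_attr = TRUE)
  expect_s3_class(suppressWarnings(normfinder_s(b2)), "stability_result")
})

test_that("drop_missing removes exactly the incomplete samples", {
  b <- rand_block(n = 16, g = 3, seed = 7)
  expect_identical(drop_missing(b), b)  # no missing: identity

  b$ct[4, 2] <- NA
  expect_message(b2 <- drop_missing(b), "dropping 1 sample")
  expect_equal(nrow(b2$ct), 15L)
  expect_error(drop_missing(b, policy = "error"), "missing Ct")

  b$ct[, 2] <- NA
  expect_error(suppressMessages(drop_missing(b)), "fewer than 3")
})

test_that("invalid Ct values are rejected at construction", {
  ct <- matrix(c(20, -1, 21, 22), 2, 2, dimnames = list(c("a", "b"), c("X", "Y")))
  expect_error(ct_matrix(ct, c("SHAM", "SHAM"), c("12h", "12h"), c("CX", "CX")),
               "finite and > 0")
})
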