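test_that("model construction enforces structure and the example web is valid", {
  m <- fw_example_web()
  expect_s3_class(m, "fw_model")
  expect_identical(nrow(m$groups), 4L)
  # every consumer diet column sums to 1
  cons <- m$groups$type == "consumer"
  expect_equal(unname(colSums(m$diet)[cons] + m$import_fraction[cons]),
               rep(1, sum(cons)))
  expect_no_violations(m)

  expect_error(fw_model(data.frame()), "non-empty")
  g <- m$groups
  g$name[2] <- g$name[1]
  expect_error(fw_model(g, m$diet), "duplicate")
  expect_error(fw_model(m$groups, m$diet[1:3, 1:3]), "4 x 4")
})

test_that("degenerate two-group web with no diet loads and validates", {
  g <- data.frame(name = c("plants", "detritus"),
                  type = c("producer", "detritus"),
                  B = c(5, 2), PB = c(10, NA))
  m <- fw_model(g)
  expect_identical(nrow(m$groups), 2L)
  expect_true(all(m$diet == 0))
  expect_no_violations(m)
})

test_that("validation reports the rule, group, and value for each violation", {
  m <- fw_example_web()
  # diet column summing to 0.8 with zero import
  m1 <- m
  m1$diet[2, 3] <- 0.8
  rep <- fw_validate(m1)
  expect_identical(nrow(rep), 1L)
  expect_match(rep$rule, "not normalized")
  expect_identical(rep$group, "herbivore")

  m2 <- m
  m2$groups$UC[3] <- 1.2
  rep2 <- fw_validate(m2)
  expect_true(any(grepl("UC outside", rep2$rule)))

  m3 <- m
  m3$groups$QB[2] <- 5   # QB on a producer
  expect_true(any(grepl("non-consumer", fw_validate(m3)$rule)))

  # validation is pure
  before <- unserialize(serialize(m1, NULL))
  invisible(fw_validate(m1))
  expect_identical(m1, before)
})

test_that("csv-pair and structured formats round-trip at full precision", {
  m <- fw_example_web()
  m$groups$B[3] <- 1 / 3           # exercise full-precision round trip
  m$groups$EE[4] <- NA             # unset stays unset, never 0

  d1 <- withr::local_tempdir()
  fw_write_model(m, d1, "csv-pair")
  m1 <- fw_read_model(d1)
  expect_equal(m1$groups$B, m$groups$B, tolerance = 0)
  expect_true(is.na(m1$groups$EE[4]))
  expect_identical(m1$groups$name, m$groups$name)
  expect_equal(unname(m1$diet), unname(m$diet))
  # save(load(x)) == save twice
  d2 <- withr::local_tempdir()
  fw_write_model(m1, d2, "csv-pair")
  expect_identical(readLines(file.path(d1, "groups.csv")),
                   readLines(file.path(d2, "groups.csv")))

  f <- withr::local_tempfile(fileext = ".json")
  fw_write_model(m, f, "structured")
  m2 <- fw_read_model(f, "structured")
  expect_equal(m2$groups$B, m$groups$B, tolerance = 0)
  expect_true(is.na(m2$groups$EE[4]))
  expect_equal(unname(m2$diet), unname(m$diet))
})

test_that("loader rejects unknown groups and non-numeric cells, save rejects empty models", {
  d <- withr::local_tempdir()
  m <- fw_example_web()
  fw_write_model(m, d, "csv-pair")
  diet <- read.csv(file.path(d, "diet.csv"), check.names = FALSE)
  names(diet)[3] <- "no-such-group"
  write.csv(diet, file.path(d, "diet.csv"), row.names = FALSE)
  expect_error(fw_read_model(d), "unknown group")

  fw_write_model(m, d, "csv-pair")
  diet <- readLines(file.path(d, "diet.csv"))
  diet[3] <- sub("1", "one", diet[3])
  writeLines(diet, file.path(d, "diet.csv"))
  expect_error(fw_read_model(d), "non-numeric")

  m0 <- fw_example_web()
  m0$groups <- m0$groups[0, ]
  expect_error(fw_write_model(m0, withr::local_tempdir()), "empty")
})

test_that("slightly denormalized diet columns are renormalized with a warning", {
  d <- withr::local_tempdir()
  m <- fw_example_web()
  m$diet[2, 3] <- 1 + 5e-4   # hand-rounded field table
  fw_write_model(m, d, "csv-pair")
  expect_warning(m2 <- fw_read_model(d), "renormalized")
  expect_equal(sum(m2$diet[, 3]), 1, tolerance = 1e-12)
})
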