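test_that("specimen reader preserves rows and validates content", {
  path <- specimen_fixture(6L)
  df <- read_specimen_table(path)
  expect_equal(nrow(df), 6L)
  expect_type(df$d13c, "double")
  expect_type(df$d15n, "double")

  # comma dialect is sniffed from the header
  df_csv <- read_specimen_table(specimen_fixture(4L, sep = ","))
  expect_equal(nrow(df_csv), 4L)

  # header-only file: empty collection with a warning
  empty <- write_fixture(list(specimen_header))
  expect_warning(df0 <- read_specimen_table(empty), "no rows")
  expect_equal(nrow(df0), 0L)

  # NA isotope value: row-level parse error citing the row
  bad <- write_fixture(list(specimen_header,
                            c("id1", "sp", "H", "S1", "B1", "-20", "5"),
                            c("id2", "sp", "H", "S1", "B1", "NA", "5")))
  expect_error(read_specimen_table(bad), "row 2")

  # missing column named in the error
  noc <- write_fixture(list(setdiff(specimen_header, "d15n"),
                            c("id1", "sp", "H", "S1", "B1", "-20")))
  expect_error(read_specimen_table(noc), "d15n")

  dup <- write_fixture(list(specimen_header,
                            c("id1", "sp", "H", "S1", "B1", "-20", "5"),
                            c("id1", "sp", "H", "S1", "B2", "-21", "6")))
  expect_error(read_specimen_table(dup), "duplicate")
})

test_that("resource reader validates SDs and uniqueness", {
  df <- read_resource_table(resource_fixture())
  expect_equal(nrow(df), 15L)

  header <- c("resource", "location", "d13c_mean", "d13c_sd",
              "d15n_mean", "d15n_sd", "n")
  neg <- write_fixture(list(header, c("r", "H", -15, -0.1, 3, 0.5, 5)))
  expect_error(read_resource_table(neg), "negative standard deviation")

  dup <- write_fixture(list(header,
                            c("r", "H", -15, 0.1, 3, 0.5, 5),
                            c("r", "H", -14, 0.1, 2, 0.5, 5)))
  expect_error(read_resource_table(dup), "r @ H")
})

test_that("census reader enforces integral counts and zero-fills on query", {
  df <- read_census_table(census_fixture())
  expect_equal(nrow(df), 48L)

  header <- c("species", "location", "litterbag", "count")
  frac <- write_fixture(list(header, c("a", "H", "B1", "3.5")))
  expect_error(read_census_table(frac), "non-integral")
  neg <- write_fixture(list(header, c("a", "H", "B1", "-1")))
  expect_error(read_census_table(neg), "negative")

  # sparse entry: absent (species, litterbag) pairs read back as zero
  sparse <- write_fixture(list(header,
                               c("a", "H", "B1", "4"),
                               c("a", "H", "B2", "2"),
                               c("b", "H", "B1", "1"),
                               c("b", "H", "B2", "0"),
                               c("b", "H", "B3", "5")))
  cen <- read_census_table(sparse)
  counts <- census_counts(cen, "a", "H")
  expect_equal(unname(counts), c(4L, 2L, 0L))
  expect_error(census_counts(cen, "a", "X"), "unknown location")
  expect_error(census_counts(cen, "zz", "H"), "unknown species")
})

test_that("mean density is total count over litterbags, with SE", {
  header <- c("species", "location", "litterbag", "count")
  two <- write_fixture(list(header,
                            c("a", "H", "B1", "2"), c("a", "H", "B2", "4")))
  d <- mean_density(read_census_table(two), "a", "H")
  expect_equal(d$mean, 3.0)
  expect_equal(d$se, sd(c(2, 4)) / sqrt(2))

  counts <- c(10, 14, 6, 8, 12, 10, 9, 11, 10, 10, 10, 10)
  rows <- lapply(seq_along(counts), function(i) {
    c("a", "H", sprintf("B%02d", i), counts[i])
  })
  d12 <- mean_density(read_census_table(write_fixture(c(list(header), rows))),
                      "a", "H")
  expect_equal(d12$mean, 10.0)
  expect_equal(d12$mean, sum(counts) / 12)  # exact total/L identity

  # all-zero counts are a legal density of 0
  zero <- write_fixture(list(header,
                             c("a", "H", "B1", "0"), c("a", "H", "B2", "0")))
  expect_equal(mean_density(read_census_table(zero), "a", "H")$mean, 0)
})

test_that("tables round-trip through the writer unchanged", {
  com <- generate_community(synthetic_config(seed = 3L))
  for (tab in c("specimens", "resources", "census")) {
    path <- tempfile(fileext = ".tsv")
    write_table(com[[tab]], path)
    reader <- switch(tab, specimens = read_specimen_table,
                     resources = read_resource_table,
                     census = read_census_table)
    back <- reader(path)
    expect_equal(back, com[[tab]], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("run configuration validates its invariants", {
  cfg <- run_config()
  expect_equal(cfg$tef_c, 0.4)
  expect_equal(cfg$tef_n, 2.3)
  expect_equal(cfg$perturbation_fraction, 0.2)
  expect_equal(cfg$n_random_matrices, 10L)
  expect_error(run_config(perturbation_fraction = 1.2))
  expect_error(run_config(mcmc = list(iterations = 100L, burnin = 200L,
                                      thin = 1L, chains = 1L)))
})
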