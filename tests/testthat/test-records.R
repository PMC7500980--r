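test_that("ingestion validates rows and reports problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,year,source",
               "sp1,1940,museumA",
               "sp2,1960,museumA",
               "sp3,1998,survey"), path)
  tab <- load_occurrences(path)
  expect_equal(nrow(tab), 3L)
  expect_type(tab$year, "integer")

  writeLines(c("species,year,source", "sp1,19xx,museumA"), path)
  expect_error(load_occurrences(path, strict = TRUE), "row 1")
  expect_warning(tab2 <- load_occurrences(path), "malformed")
  expect_equal(nrow(tab2), 0L)
  expect_equal(attr(tab2, "problems")$row, 1L)

  writeLines(c("taxon,year,source", "sp1,1940,m"), path)
  expect_error(load_occurrences(path), "required column")
})

test_that("duplicate records collapse to a single incidence cell", {
  rec <- occurrence_table(c("sp1", "sp1"), c(1940, 1941), "m")
  lab <- assign_time_layers(rec, default_layer_scheme())
  inc <- build_incidence(lab)
  expect_equal(dim(inc), c(1L, 1L))
  expect_equal(unname(inc[1, 1]), 1L)
})

test_that("phenological filter removes flagged species and is monotone", {
  tt <- tiny_traits()
  rec <- tiny_records()
  same <- apply_phenological_filter(rec, tt)
  expect_equal(nrow(same), nrow(rec))  # nothing flagged

  tt$long_distance_migrant[2] <- TRUE
  filt <- apply_phenological_filter(rec, tt)
  expect_false("sp2" %in% filt$species_id)
  expect_equal(attr(filt, "removed")$reason, "long_distance_migrant")

  # adding a flag never increases the surviving record count
  tt2 <- tt
  tt2$strictly_diurnal[4] <- TRUE
  expect_lte(nrow(apply_phenological_filter(rec, tt2)), nrow(filt))

  tt3 <- tt
  tt3$early_late_flyer <- TRUE
  expect_warning(empty <- apply_phenological_filter(rec, tt3),
                 "all species removed")
  expect_equal(nrow(empty), 0L)

  expect_error(
    apply_phenological_filter(
      occurrence_table("ghost", 1950), tt, unknown_species = "error"),
    "ghost")
})

test_that("years map to the documented museum partitions and survey years", {
  scheme <- default_layer_scheme()
  rec <- occurrence_table(c("a", "b", "c", "d", "e"),
                          c(1940, 1976, 2011, 1933, 1985))
  lab <- assign_time_layers(rec, scheme)
  expect_equal(lab$layer, c("1940s", "1960s", "2011", "1940s", "1980s"))

  expect_warning(out <- assign_time_layers(
    occurrence_table("a", 2050), scheme), "rejected")
  expect_equal(nrow(out), 0L)
})

test_that("layer schemes reject overlap and inverted spans", {
  expect_error(time_layer_scheme(data.frame(
    label = c("A", "B"), year_min = c(1930, 1940), year_max = c(1945, 1950))),
    "overlap")
  expect_error(time_layer_scheme(data.frame(
    label = "A", year_min = 1950, year_max = 1940)), "year_min")
})

test_that("incidence construction is invariant to record order", {
  rec <- tiny_records()
  scheme <- default_layer_scheme()
  inc1 <- build_incidence(assign_time_layers(rec, scheme))
  set.seed(42)
  shuffled <- rec[sample(nrow(rec)), , drop = FALSE]
  inc2 <- build_incidence(assign_time_layers(shuffled, scheme))
  expect_identical(inc1, inc2)
  expect_error(build_incidence(rec), "layer")
})

test_that("status partition follows the cut-year rule and is exhaustive", {
  rec <- tiny_records()
  inc <- build_incidence(assign_time_layers(rec, default_layer_scheme()))
  st <- assign_status(inc, cut_year = 1997)
  got <- setNames(as.character(st$status), st$species_id)
  expect_equal(got[["sp1"]], "lost")              # 1940, 1995 only
  expect_equal(got[["sp2"]], "lost")
  expect_equal(got[["sp3"]], "previously_unrecorded")  # 1998 and 2011
  expect_equal(got[["sp5"]], "previously_unrecorded")
  expect_equal(sum(attr(st, "counts")), nrow(inc))

  # a species seen in the 1980s and in 2011 spans the cut: persistent;
  # records in the cut year itself count as post-cut
  rec97 <- occurrence_table(c("x", "x", "y", "y"),
                            c(1986, 2011, 1990, 1997))
  inc97 <- build_incidence(assign_time_layers(rec97, default_layer_scheme()))
  st97 <- assign_status(inc97, cut_year = 1997)
  expect_equal(as.character(st97$status), c("persistent", "persistent"))
})

test_that("status is invariant to merging layers on one side of the cut", {
  rec <- tiny_records()
  fine <- default_layer_scheme()
  coarse <- time_layer_scheme(data.frame(
    label = c("historic", "recent"),
    year_min = c(1933, 1997), year_max = c(1996, 2012)))
  st1 <- assign_status(build_incidence(assign_time_layers(rec, fine)))
  st2 <- assign_status(build_incidence(assign_time_layers(rec, coarse)),
                       scheme = coarse)
  expect_equal(st1$status, st2$status[match(st1$species_id,
                                            st2$species_id)])

  straddle <- time_layer_scheme(data.frame(
    label = "all", year_min = 1933, year_max = 2012))
  expect_error(
    assign_status(build_incidence(assign_time_layers(rec, straddle)),
                  scheme = straddle),
    "straddle")
})
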