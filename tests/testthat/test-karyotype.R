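test_that("karyotype formulas parse in all three dialect forms", {
  expect_equal(parse_karyotype_formula("38m-sm/2st-a"),
               c(biarmed = 38L, uniarmed = 2L))
  expect_equal(parse_karyotype_formula("38st-a"),
               c(biarmed = 0L, uniarmed = 38L))
  expect_equal(parse_karyotype_formula("34m-sm/4st-a"),
               c(biarmed = 34L, uniarmed = 4L))
  expect_equal(parse_karyotype_formula("40m-sm"),
               c(biarmed = 40L, uniarmed = 0L))
})

test_that("malformed formulas fail naming the offending token", {
  expect_error(parse_karyotype_formula("38m-sm/2sta"), "2sta")
  expect_error(parse_karyotype_formula("xm-sm"), "xm-sm")
  expect_error(parse_karyotype_formula(""), "malformed")
})

test_that("parse -> serialize -> parse round-trips valid formulas", {
  set.seed(11)
  for (i in 1:50) {
    b <- sample(0:40, 1); u <- sample(0:40, 1)
    if (b + u == 0) u <- 2
    kf <- format_karyotype_formula(b, u)
    expect_equal(unname(parse_karyotype_formula(kf)), c(b, u))
    expect_identical(format_karyotype_formula(
      parse_karyotype_formula(kf)[["biarmed"]],
      parse_karyotype_formula(kf)[["uniarmed"]]), kf)
  }
})

test_that("fundamental number is 2n plus the bi-armed count", {
  expect_equal(fundamental_number(
    karyotype_record("a", 40, biarmed = 38, uniarmed = 2)), 78)
  expect_equal(fundamental_number(
    karyotype_record("b", 38, biarmed = 0, uniarmed = 38)), 38)
  expect_equal(fundamental_number(
    karyotype_record("c", 36, "6m-sm/30st-a")), 42)
})

test_that("record invariants are enforced", {
  expect_error(karyotype_record("x", 40, biarmed = 10, uniarmed = 10),
               "sum to the diploid number")
  expect_error(karyotype_record("x", 1, biarmed = 1, uniarmed = 0), ">= 2")
  expect_error(karyotype_record("x", 10, biarmed = 10, uniarmed = 0,
                                ch_bands = "int:9q"), "exceeds")
  r <- karyotype_record("x", 40, "8m-sm/32st-a")
  expect_gte(r$fundamental_number, r$diploid_number)
  expect_lte(r$fundamental_number, 2 * r$diploid_number)
})

test_that("divergence index matches the |d2n|/2 + |dFN|/2 formula", {
  beebei <- karyotype_record("beebei", 40, "8m-sm/32st-a")
  hamiltoni <- karyotype_record("hamiltoni", 36, "6m-sm/30st-a")
  expect_equal(divergence_index(beebei, hamiltoni), 5)
  expect_equal(divergence_index(beebei, beebei), 0)
})

test_that("divergence index is a semimetric on random karyotypes", {
  set.seed(42)
  for (i in 1:40) {
    a <- random_karyotype(); b <- random_karyotype()
    d <- divergence_index(a, b)
    expect_gte(d, 0)
    expect_equal(d, divergence_index(b, a))
    same <- a$diploid_number == b$diploid_number &&
      a$fundamental_number == b$fundamental_number
    expect_equal(d == 0, same)
    expect_lte(a$fundamental_number, 2 * a$diploid_number)
    expect_gte(a$fundamental_number, a$diploid_number)
  }
})

test_that("divergence matrix is symmetric with zero diagonal", {
  r <- lapply(c(40, 38, 36), function(d)
    karyotype_record(paste0("sp", d), d, biarmed = 0, uniarmed = d))
  m <- divergence_matrix(r)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(sp40 = 0, sp38 = 0, sp36 = 0))
  expect_setequal(m[upper.tri(m)], c(2, 2, 4))
  two <- list(karyotype_record("a", 40, "40st-a"),
              karyotype_record("b", 40, "40st-a"))
  expect_equal(unname(divergence_matrix(two)), matrix(0, 2, 2))
  dup <- list(karyotype_record("a", 40, "40st-a"),
              karyotype_record("a", 38, "38st-a"))
  expect_error(divergence_matrix(dup), "duplicate")
})

test_that("the packaged karyotype table reproduces the published zeros", {
  recs <- select_sex(fixture_records())
  expect_length(recs, 11)
  m <- divergence_matrix(recs)
  expect_equal(m["Brachyhypopomus_bennetti", "Brachyhypopomus_walteri"], 0)
  expect_equal(m["Brachyhypopomus_pinnicaudatus",
                 "Brachyhypopomus_gauderio"], 0)
  expect_equal(m["Brachyhypopomus_beebei", "Brachyhypopomus_hamiltoni"], 5)
})

test_that("CH band comparison partitions the union of band sets", {
  a <- karyotype_record("a", 40, "40st-a", ch_bands = "cen:all;int:2q")
  expect_equal(compare_ch_bands(a, a), c(shared = 2L, a_only = 0L,
                                         b_only = 0L))
  b <- karyotype_record("b", 40, "40st-a", ch_bands = "dist:9p")
  a1 <- karyotype_record("a1", 40, "40st-a", ch_bands = "prox:7q")
  expect_equal(compare_ch_bands(a1, b), c(shared = 0L, a_only = 1L,
                                          b_only = 1L))
  recs <- fixture_records()
  cmpb <- compare_ch_bands(record_by_species(recs, "bennetti"),
                           record_by_species(recs, "walteri"))
  expect_equal(cmpb[["shared"]], 2L)
  expect_equal(cmpb[["b_only"]], 13L)
  expect_equal(cmpb[["a_only"]], 0L)
})

test_that("sex selection prefers the requested complement", {
  recs <- fixture_records()
  f <- select_sex(recs, "female")
  m <- select_sex(recs, "male")
  sp <- vapply(f, function(r) r$species, character(1))
  pinn_f <- f[[match("Brachyhypopomus_pinnicaudatus", sp)]]
  pinn_m <- m[[match("Brachyhypopomus_pinnicaudatus", sp)]]
  expect_equal(pinn_f$diploid_number, 42L)
  expect_equal(pinn_m$diploid_number, 41L)
  expect_equal(diploid_numbers(recs)[["Brachyhypopomus_flavipomus"]], 44)
})

test_that("karyotype tables round-trip through TSV", {
  recs <- fabricate_karyotype_table(6, seed = 9)
  path <- tempfile(fileext = ".tsv")
  write_karyotype_table(recs, path)
  back <- read_karyotype_table(path)
  expect_equal(length(back), 6L)
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$diploid_number, recs[[i]]$diploid_number)
    expect_equal(back[[i]]$biarmed_count, recs[[i]]$biarmed_count)
    expect_equal(back[[i]]$ch_bands, recs[[i]]$ch_bands)
  }
})

test_that("divergence matrices round-trip through square TSV", {
  m <- divergence_matrix(select_sex(fixture_records()))
  path <- tempfile(fileext = ".tsv")
  write_divergence_matrix(m, path)
  expect_equal(read_divergence_matrix(path), m)
})
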