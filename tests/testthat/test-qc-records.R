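test_that("constructor sorts orbitals and extracts the frontier pair", {
  rec <- qc_record("cellulose", c(1.442, -6.502, 3, -8),
                   c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(rec$orbital_energies, c(-8, -6.502, 1.442, 3))
  expect_equal(unname(homo_lumo(rec)), c(-6.502, 1.442))

  # permutation of the input orbital list never changes the frontier pair
  set.seed(42)
  e <- c(-9, -7, -5.5, -4.244, -4.076, -2, 0.5)
  occ <- e <= -4.244
  for (i in 1:10) {
    p <- sample(length(e))
    expect_equal(unname(homo_lumo(qc_record("x", e[p], occ[p]))),
                 c(-4.244, -4.076))
  }

  expect_equal(unname(homo_lumo(frontier_record("m", -1, 1))), c(-1, 1))
})

test_that("validation rejects malformed records", {
  expect_error(qc_record("", c(-1, 1), c(TRUE, FALSE)), "non-empty")
  expect_error(qc_record("x", c(-1, 1), c(TRUE)), "same length")
  # occupied orbital at or above a virtual one is a hard error
  expect_error(qc_record("x", c(-1, -2), c(TRUE, FALSE)), "occupied")
  expect_error(qc_record("x", c(0, 0), c(TRUE, FALSE)), "occupied")
  # population weight rows must sum to 1
  w <- rbind(c(0.5, 0.3), c(0.5, 0.5))  # first row sums to 0.8
  expect_error(qc_record("x", c(-1, 1), c(TRUE, FALSE), population_weights = w),
               "row 1 sums to 0.8")
  expect_error(homo_lumo(qc_record("x", c(-1, -2), c(TRUE, TRUE))),
               "no virtual")
})

test_that("imaginary modes are carried with a warning flag", {
  expect_warning(rec <- qc_record("ts", c(-1, 1), c(TRUE, FALSE),
                                  frequencies = c(-50, 1000)),
                 "imaginary")
  expect_true(rec$has_imaginary)
  expect_equal(rec$frequencies, c(-50, 1000))
})

test_that("canonical JSON serialization round-trips and is deterministic", {
  w <- matrix(c(0.2, 0.8, 0.5, 0.5, 1/3, 2/3), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("C", "O")))
  rec <- qc_record("cellulose", c(-8.1, -6.502, 1.442), c(TRUE, TRUE, FALSE),
                   method = "B3LYP", basis = "3-21G**",
                   total_energy = -1898.381, dipole = c(1, 2, 2),
                   frequencies = c(615, 2900.25), population_weights = w)
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_record(rec, path)
  back <- read_qc_record(path)
  expect_equal(back[setdiff(names(back), "population_weights")],
               rec[setdiff(names(rec), "population_weights")])
  expect_equal(unname(back$population_weights), unname(rec$population_weights))

  # write(parse(write(x))) is byte-identical: canonical key order and
  # full-precision floats
  expect_identical(write_qc_record(back), write_qc_record(rec))
  expect_identical(write_qc_record(rec), write_qc_record(rec))

  # optional fields are omitted, not serialized as null
  bare <- qc_record("b", c(-1, 1), c(TRUE, FALSE))
  txt <- write_qc_record(bare)
  expect_false(grepl("total_energy|dipole|frequencies|population", txt))
  expect_equal(read_qc_record(txt)$label, "b")
})

test_that("parse errors name the missing field and re-validate invariants", {
  expect_error(read_qc_record('{"label": "x"}'), "orbital_energies")
  expect_error(read_qc_record('{"orbital_energies": [1], "occupied": [true]}'),
               "label")
  bad <- '{"label":"x","orbital_energies":[-1,-2],"occupied":[true,false]}'
  expect_error(read_qc_record(bad), "occupied")
})

test_that("record sets enforce unique labels and round-trip through JSON", {
  a <- frontier_record("a", -2, 1)
  b <- frontier_record("b", -3, 0.5)
  expect_error(record_set(list(a, a)), "duplicate")
  rs <- record_set(list(a, b), provenance = "test")
  expect_equal(length(rs), 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_record_set(rs, path)
  back <- read_record_set(path)
  expect_equal(names(back$records), c("a", "b"))
  expect_equal(back$records$a$orbital_energies, a$orbital_energies)
  expect_equal(back$provenance, "test")
})

test_that("occupied/virtual split partitions and sorts", {
  rec <- qc_record("go", c(-5, -4.244, -4.076, -3.5),
                   c(TRUE, TRUE, FALSE, FALSE))
  sp <- split_occupied_virtual(rec)
  expect_equal(sp$occupied, c(-5, -4.244))
  expect_equal(sp$virtual, c(-4.076, -3.5))
  # both occupied and virtual states can sit below 0 on the absolute scale
  expect_true(all(sp$virtual < 0))

  all_occ <- qc_record("core", c(-3, -2, -1), c(TRUE, TRUE, TRUE))
  expect_length(split_occupied_virtual(all_occ)$virtual, 0L)
})
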