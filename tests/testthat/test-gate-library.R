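test_that("builtin library matches the checked-in parameter transcription", {
  lib <- builtin_library()
  expect_equal(nrow(lib$gates), 18)
  ref <- utils::read.table(
    system.file("extdata", "gate_parameters.tsv", package = "norcircuit"),
    sep = "\t", header = TRUE, colClasses = c(rep("character", 2), rep("numeric", 8)))
  expect_identical(lib$gates$name, ref$name)
  expect_identical(lib$gates$family, ref$family)
  for (col in c("y_min", "y_max", "K", "n", "alpha", "beta", "tau_on", "tau_off"))
    expect_identical(lib$gates[[col]], ref[[col]], label = col)
})

test_that("builtin library carries the characterized sensors and layout rules", {
  lib <- builtin_library()
  cin <- dplyr::filter(lib$sensors, name == "P_Cin")
  expect_equal(cin$off_rpu, 0.005)
  expect_equal(cin$on_rpu, 3.178)
  tac <- dplyr::filter(lib$sensors, name == "P_Tac")
  expect_equal(c(tac$off_rpu, tac$on_rpu), c(0.008, 1.686))
  phlf <- dplyr::filter(lib$gates, name == "P1-PhlF")
  expect_equal(unlist(phlf[, 3:10], use.names = FALSE),
               c(0.004, 6.9, 0.04, 3.8, 0.22, 0.06, 0.30, 4.00))
  expect_true(any(vapply(lib$layout$prohibited_pairs,
                         function(p) setequal(p, c("CymR", "SrpR")),
                         logical(1))))
  expect_equal(lib$layout$scar_order[1], "A")
  expect_equal(utils::tail(lib$layout$scar_order, 1), "C")
  expect_equal(lib$layout$gate_order,
               c("VanR", "PhlF", "SrpR", "AmtR", "AmeR",
                 "BM3R1", "LmrA", "HlyIIR", "BetI", "CymR"))
  expect_equal(nrow(validate_library(lib)), 0)
})

test_that("validate_library reports record-level violations without raising", {
  lib <- builtin_library()
  bad <- lib
  bad$gates$y_min[1] <- bad$gates$y_max[1] + 1
  expect_match(validate_library(bad)$issue, "y_min < y_max")

  bad <- lib
  bad$gates$alpha[2] <- 1.2
  expect_match(validate_library(bad)$issue, "alpha")

  bad <- lib
  bad$gates$name[2] <- bad$gates$name[1]
  expect_match(validate_library(bad)$issue, "duplicate")

  empty <- lib
  empty$gates <- lib$gates[0, ]
  expect_match(validate_library(empty)$issue, "empty")
})

test_that("the packaged library fixture loads to the builtin library", {
  path <- system.file("extdata", "eco_nor_library.json", package = "norcircuit")
  lib <- read_gate_library(path)
  ref <- builtin_library()
  expect_equal(lib$gates, ref$gates)
  expect_equal(lib$sensors, ref$sensors)
  expect_equal(lib$layout$gate_order, ref$layout$gate_order)
  expect_equal(lib$layout$prohibited_pairs, ref$layout$prohibited_pairs)
})

test_that("write/read round-trips randomized libraries exactly", {
  set.seed(42)
  for (i in 1:10) {
    lib <- random_library(n_gates = sample(2:8, 1), n_sensors = sample(1:3, 1))
    path <- withr::local_tempfile(fileext = ".json")
    write_gate_library(lib, path)
    back <- read_gate_library(path)
    expect_equal(back$gates, lib$gates)
    expect_equal(back$sensors, lib$sensors)
    expect_equal(back$layout$gate_order, lib$layout$gate_order)
    expect_equal(back$layout$scar_order, lib$layout$scar_order)
    expect_equal(back$layout$prohibited_pairs, lib$layout$prohibited_pairs)
    expect_equal(back$reporter, lib$reporter)
  }
})

test_that("unknown record fields survive a read/modify/write cycle", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- jsonlite::fromJSON(
    system.file("extdata", "eco_nor_library.json", package = "norcircuit"),
    simplifyVector = FALSE)
  doc$gates[[1]]$dna_length <- 1234
  doc$custom_block <- list(note = "foreign extension")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  lib <- read_gate_library(path)
  expect_equal(lib$metadata$extra$gates[[lib$gates$name[1]]]$dna_length, 1234)
  expect_equal(lib$metadata$extra$top$custom_block$note, "foreign extension")
  path2 <- withr::local_tempfile(fileext = ".json")
  write_gate_library(lib, path2)
  back <- jsonlite::fromJSON(path2, simplifyVector = FALSE)
  expect_equal(back$gates[[1]]$dna_length, 1234)
  expect_equal(back$custom_block$note, "foreign extension")
})

test_that("a record without an interference block reverts to the additive limit", {
  path <- withr::local_tempfile(fileext = ".json")
  lib <- random_library(n_gates = 3)
  write_gate_library(lib, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$gates[[2]]$interference <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  back <- read_gate_library(path)
  expect_equal(back$gates$alpha[2], 1)
  expect_equal(back$gates$beta[2], 1)
})

test_that("malformed library files raise named parse errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", path)
  expect_error(read_gate_library(path), "parse failure")
  jsonlite::write_json(list(format = "norcircuit-library", gates = list()),
                       path, auto_unbox = TRUE)
  expect_error(read_gate_library(path), "empty")
  jsonlite::write_json(list(gates = list(list(name = "g"))), path,
                       auto_unbox = TRUE)
  expect_error(read_gate_library(path), "format")
})
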