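number_mutants <- function(ref, specs) {
  # specs: list of integer vectors of Kabat numbers -> mutate to fixed "Q"/"A"
  lapply(seq_along(specs), function(i) {
    pos <- specs[[i]]$pos
    to <- specs[[i]]$to
    assign_numbering(mutate_germline(ref, pos, to), ref,
                     source_id = sprintf("m%02d", i))
  })
}

test_that("tallying counts each (position, from, to) once per carrying sequence", {
  # 10 sequences, 3 carrying M4L, 2 carrying T5A, plus germline copies
  specs <- c(
    replicate(3, list(list(pos = 4, to = "L"))),
    replicate(2, list(list(pos = 5, to = "A"))),
    replicate(5, list(list(pos = integer(0), to = character(0))))
  )
  reps <- number_mutants(ref_kappa1, specs)
  obs <- tally_natural_diversity(reps, ref_kappa1)
  expect_equal(nrow(obs), 2L)
  m4l <- obs[obs$number == 4, ]
  expect_equal(m4l$count, 3L)
  expect_equal(m4l$from_aa, "M")
  expect_equal(m4l$to_aa, "L")
  expect_equal(obs$count[obs$number == 5], 2L)

  # two distinct substitutions at one position count independently
  specs2 <- list(
    list(pos = 4, to = "L"), list(pos = 4, to = "L"), list(pos = 4, to = "V")
  )
  obs2 <- tally_natural_diversity(number_mutants(ref_kappa1, specs2), ref_kappa1)
  expect_equal(obs2$to_aa, c("L", "V"))
  expect_equal(obs2$count, c(2L, 1L))

  # germline-only repertoire tallies to nothing; empty repertoire is fine
  expect_equal(nrow(tally_natural_diversity(number_mutants(ref_kappa1,
    replicate(3, list(list(pos = integer(0), to = character(0))))), ref_kappa1)), 0L)
  expect_equal(nrow(tally_natural_diversity(list(), ref_kappa1)), 0L)
})

test_that("design filters implement the buried-framework truth table", {
  obs <- data.frame(
    chain = "heavy",
    number = c(6L, 17L, 48L, 70L, 89L, 33L, 52L, 40L, 74L, 6L),
    insertion = "",
    from_aa = c("E", "T", "V", "V", "A", "A", "S", "A", "S", "E"),
    to_aa =   c("Q", "S", "I", "A", "G", "T", "N", "V", "T", "D"),
    count = c(5L, 2L, 9L, 1L, 3L, 4L, 2L, 6L, 2L, 1L),
    stringsAsFactors = FALSE
  )
  # buried: 6, 17, 48, 70, 89, 33, 52; exposed: 40, 74
  burial <- data.frame(
    chain = "heavy",
    number = c(6L, 17L, 48L, 70L, 89L, 33L, 52L, 40L, 74L),
    rsa = c(rep(0.05, 7), 0.6, 0.8)
  )
  cfg <- design_config(rsa_max = 0.2, min_count = 1)
  lib <- design_library(obs, burial, cfg)
  # expected: buried FR positions only -> 6(Q), 6(D), 17, 48, 70, 89;
  # 33 (CDR1) and 52 (CDR2) fall to the framework filter, 40/74 to burial
  expect_setequal(lib$name, c("E6Q", "E6D", "T17S", "V48I", "V70A", "A89G"))
  log <- attr(lib, "filter_log")
  expect_equal(log$failed_filters[log$position == "33"], "non-framework")
  expect_equal(log$failed_filters[log$position == "40"], "surface-exposed")

  # raising min_count and excluding positions shrink the library monotonically
  lib2 <- design_library(obs, burial, design_config(min_count = 2))
  expect_true(all(lib2$name %in% lib$name))
  expect_false("V70A" %in% lib2$name) # count 1
  lib3 <- design_library(obs, burial,
                         design_config(excluded_positions = c(48L)))
  expect_true(all(lib3$name %in% lib$name))
  expect_false("V48I" %in% lib3$name)

  # widening rsa_max only adds variants (nested outputs)
  lib4 <- design_library(obs, burial, design_config(rsa_max = 0.7))
  expect_true(all(lib$name %in% lib4$name))
  expect_true("A40V" %in% lib4$name)
})

test_that("missing burial annotations follow the configured policy", {
  obs <- data.frame(
    chain = "heavy", number = 6L, insertion = "", from_aa = "E", to_aa = "Q",
    count = 2L, stringsAsFactors = FALSE
  )
  nob <- data.frame(chain = "heavy", number = 99L, rsa = 0.1)
  expect_equal(nrow(design_library(obs, nob, design_config())), 0L)
  expect_error(
    design_library(obs, nob, design_config(missing_burial = "error")),
    "missing burial"
  )
})

test_that("library files round-trip exactly and validate names", {
  obs <- data.frame(
    chain = c("light", "heavy"), number = c(4L, 6L), insertion = "",
    from_aa = c("M", "E"), to_aa = c("L", "Q"), count = c(3L, 5L),
    stringsAsFactors = FALSE
  )
  burial <- rbind(
    data.frame(chain = "light", number = 4L, rsa = 0.1),
    data.frame(chain = "heavy", number = 6L, rsa = 0.1)
  )
  lib <- design_library(obs, burial)
  tmp <- tempfile(fileext = ".tsv")
  write_library(lib, tmp)
  back <- read_library(tmp)
  expect_equal(back$name, lib$name)
  expect_equal(back$support, lib$support)
  expect_equal(back$chain, lib$chain)
  # byte-identical on rewrite (deterministic serialization)
  tmp2 <- tempfile(fileext = ".tsv")
  write_library(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
  # empty library round-trips
  empty <- design_library(obs[0, ], burial)
  write_library(empty, tmp)
  expect_equal(nrow(read_library(tmp)), 0L)
  # corrupted name is caught
  lines <- readLines(tmp2)
  lines <- sub("M4L", "M5L", lines)
  writeLines(lines, tmp2)
  expect_error(read_library(tmp2), "does not match")
})
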