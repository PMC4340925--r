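test_that("genotype tokens parse into canonical distinct-allele sets", {
  # homozygous SNP collapses to one distinct allele
  expect_identical(parse_genotype_token("AA", "snp"), "A")
  expect_identical(parse_genotype_token("AB", "snp"), "A/B")
  expect_identical(parse_genotype_token("ba", "snp"), "A/B")
  expect_identical(parse_genotype_token("GT", "snp"), "G/T")
  # no-call dialect, case-insensitive
  for (tok in c("No Call", "NC", "nocall", "", "—", NA)) {
    expect_true(is.na(parse_genotype_token(tok, "snp")), info = tok)
    expect_true(is.na(parse_genotype_token(tok, "str")), info = tok)
  }
  # STR allele lists with microvariants and trailing-zero normalisation
  expect_identical(parse_genotype_token("9,9.3", "str"), "9/9.3")
  expect_identical(parse_genotype_token("9.30", "str"), "9.3")
  expect_identical(parse_genotype_token("12, 12", "str"), "12")
  expect_identical(parse_genotype_token("X, Y", "str"), "X/Y")
  # unparseable tokens raise classed errors, never coerce
  expect_error(parse_genotype_token("AAB?", "snp"), class = "cellauth_parse_error")
  expect_error(parse_genotype_token("abc", "str"), class = "cellauth_parse_error")
})

test_that("STR alleles sort numerically and genotype() rejects empty sets", {
  expect_identical(genotype(c("10", "9.3", "9")), "9/9.3/10")
  expect_identical(genotype(c("Y", "X")), "X/Y")
  expect_error(genotype(character(0)))
  expect_error(genotype(NA))
})

test_that("profile tables round-trip exactly through write and read", {
  panel <- dplyr::bind_rows(
    snptrace_panel(n_fingerprint = 3, n_ancestry = 2, n_x = 1, n_y = 1),
    powerplex_panel()[c(1, 16), ]
  )
  pop <- generate_population(synth_config(
    n_individuals = 3, n_fingerprint = 3, n_ancestry = 2, n_x = 1, n_y = 1,
    n_replicates = 0, n_synonymous = 0, no_call_rate = 0.2, seed = 11
  ))
  strs <- tibble::tibble(
    sample_id = rep(pop$annotations$sample_id, each = 2),
    marker_id = rep(c("D3S1358", "AMEL"), 3),
    genotype = c("9/9.3", "X/Y", "12", "X", NA, "X/Y")
  )
  profiles <- dplyr::bind_rows(pop$profiles, strs)
  ann <- pop$annotations
  ann$replicate_group[1] <- "rg1"

  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_table(profiles, ann, panel, path)
  back <- read_profile_table(path, panel)

  orig <- dplyr::arrange(profiles, match(sample_id, ann$sample_id),
                         match(marker_id, panel$marker_id))
  expect_equal(as.data.frame(back$profiles), as.data.frame(orig))
  expect_equal(as.data.frame(back$annotations), as.data.frame(ann))

  # overwrite guard
  expect_error(write_profile_table(profiles, ann, panel, path), "exists")
  expect_no_error(write_profile_table(profiles, ann, panel, path,
                                      overwrite = TRUE))

  # tsv dialect round-trips the same way
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_profile_table(profiles, ann, panel, path2)
  back2 <- read_profile_table(path2, panel)
  expect_equal(as.data.frame(back2$profiles), as.data.frame(orig))
})

test_that("an empty profile list writes a header-only file", {
  panel <- snptrace_panel(n_fingerprint = 2, n_ancestry = 0, n_x = 1, n_y = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_table(
    tibble::tibble(sample_id = character(), marker_id = character(),
                   genotype = character()),
    tibble::tibble(sample_id = character(), cell_line_name = character(),
                   clid = character(), annotated_sex = character(),
                   replicate_type = character(), replicate_group = character(),
                   synonym_group = character()),
    panel, path
  )
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "rs100001")
})

test_that("reader errors name missing markers, duplicates and bad tokens", {
  panel <- snptrace_panel(n_fingerprint = 2, n_ancestry = 0, n_x = 1, n_y = 1)
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("sample_id,rs100001", "s1,AA"), path)
  expect_error(read_profile_table(path, panel),
               class = "cellauth_panel_mismatch")
  expect_error(read_profile_table(path, panel), "rs100002")

  writeLines(c(
    "sample_id,rs100001,rs100002,rs200001,rs300001",
    "s1,AA,AB,AA,A",
    "s1,AB,AA,AB,A"
  ), path)
  expect_error(read_profile_table(path, panel), "duplicate sample_id")

  writeLines(c(
    "sample_id,rs100001,rs100002,rs200001,rs300001",
    "s1,AA,??,AA,A"
  ), path)
  expect_error(read_profile_table(path, panel), "rs100002",
               class = "cellauth_parse_error")
  lenient <- read_profile_table(path, panel, strict = FALSE)
  expect_true(is.na(
    lenient$profiles$genotype[lenient$profiles$marker_id == "rs100002"]
  ))
  expect_identical(attr(lenient$profiles, "parse_errors")$token, "??")
})

test_that("parsing is order-independent: permuting rows permutes outputs", {
  panel <- snptrace_panel(n_fingerprint = 3, n_ancestry = 0, n_x = 1, n_y = 1)
  header <- paste(c("sample_id", panel$marker_id), collapse = ",")
  rows <- c("s1,AA,AB,BB,AA,A", "s2,AB,NC,AA,AB,No Call", "s3,BB,BB,AB,AA,A")
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header, rows), p1)
  writeLines(c(header, rev(rows)), p2)
  r1 <- read_profile_table(p1, panel)
  r2 <- read_profile_table(p2, panel)
  expect_identical(r1$annotations$sample_id, c("s1", "s2", "s3"))
  expect_identical(r2$annotations$sample_id, c("s3", "s2", "s1"))
  reordered <- dplyr::arrange(r2$profiles, sample_id, marker_id)
  expect_equal(as.data.frame(dplyr::arrange(r1$profiles, sample_id, marker_id)),
               as.data.frame(reordered))
})

test_that("call-rate accounting is exact: calls + no-calls = samples x markers", {
  pop <- generate_population(synth_config(
    n_individuals = 40, no_call_rate = 0.05, n_replicates = 0,
    n_synonymous = 0, seed = 3
  ))
  rep_ <- validate_profiles(pop$profiles, pop$panel)
  expect_identical(rep_$n_calls + rep_$n_no_calls, 40L * 90L)
  expect_equal(rep_$call_rate, 1 - rep_$n_no_calls / (40 * 90))
  expect_identical(sum(tidy(rep_)$n_no_call), rep_$n_no_calls)

  # degenerate corners
  all_called <- tibble::tibble(sample_id = "s", marker_id = pop$panel$marker_id,
                               genotype = "A")
  expect_equal(validate_profiles(all_called, pop$panel)$call_rate, 1)
  none <- tibble::tibble(sample_id = "s", marker_id = pop$panel$marker_id,
                         genotype = NA_character_)
  expect_equal(validate_profiles(none, pop$panel)$call_rate, 0)
})
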