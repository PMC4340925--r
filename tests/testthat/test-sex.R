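allosome_profile <- function(id, y = c(NA, NA, NA), x = c("A", "A/B", "B")) {
  tibble::tibble(
    sample_id = id,
    marker_id = c(paste0("rs30000", 1:3), paste0("rs20000", 1:3)),
    genotype = c(y, x)
  )
}

sex_panel <- snptrace_panel(n_fingerprint = 2, n_ancestry = 0, n_x = 3, n_y = 3)

test_that("allosome SNP rule: two chrY calls make a male, none a female", {
  profs <- dplyr::bind_rows(
    allosome_profile("male_full", y = c("A", "A", "B")),
    allosome_profile("male_one_fail", y = c("A", NA, "B")),
    allosome_profile("female_full", y = c(NA, NA, NA)),
    allosome_profile("ambiguous", y = c("A", NA, NA), x = c("A", NA, NA)),
    allosome_profile("assay_dropout", y = c(NA, NA, NA), x = c("A", NA, NA))
  )
  calls <- sex_from_snp_panel(profs, sex_panel)
  got <- setNames(as.character(calls$call), calls$sample_id)
  expect_identical(got[["male_full"]], "male")
  # redundancy: one failed Y assay still types male
  expect_identical(got[["male_one_fail"]], "male")
  expect_identical(got[["female_full"]], "female")
  # a single chrY call is not enough evidence either way
  expect_identical(got[["ambiguous"]], "no_call")
  # too few valid X assays cannot confirm a female
  expect_identical(got[["assay_dropout"]], "no_call")
  # evidence counts always populated
  expect_identical(calls$n_y_called[calls$sample_id == "male_one_fail"], 2L)
  expect_identical(calls$n_y_total, rep(3L, 5))
})

test_that("amelogenin rule: {X} female, {X,Y} male, rest no_call", {
  profs <- tibble::tibble(
    sample_id = c("f", "m", "dropout", "implausible"),
    marker_id = "AMEL",
    genotype = c("X", "X/Y", NA, "Y")
  )
  calls <- sex_from_str(profs)
  expect_identical(as.character(calls$call),
                   c("female", "male", "no_call", "no_call"))
  expect_identical(calls$amelogenin, c("X", "X/Y", NA, "Y"))
  expect_error(sex_from_str(profs[0, ]), "AMEL")
})

test_that("array rule joins low chrX heterozygosity with chrY copy signal", {
  feats <- tibble::tibble(
    sample_id = c("xy", "xx", "y_low_mosaic", "borderline", "missing"),
    het_fraction_x = c(0.02, 0.30, 0.02, 0.05, NA),
    y_cn_ratio = c(0.80, 0.05, 0.40, 0.51, 0.9)
  )
  calls <- sex_from_array(feats)
  got <- setNames(as.character(calls$call), calls$sample_id)
  expect_identical(got[["xy"]], "male")
  expect_identical(got[["xx"]], "female")
  # the known false-negative mode: a minor Y-bearing subpopulation keeps
  # the copy-number ratio under the cutoff and the sample types female
  expect_identical(got[["y_low_mosaic"]], "female")
  # cutoffs are <= for het and strictly > for Y copy number
  expect_identical(got[["borderline"]], "male")
  expect_identical(got[["missing"]], "no_call")
})

test_that("platform calls use only their own evidence", {
  # same sample, contradictory platforms: each caller sticks to its input
  snp <- allosome_profile("s", y = c("A", "A", "A"))
  str_ <- tibble::tibble(sample_id = "s", marker_id = "AMEL", genotype = "X")
  expect_identical(as.character(sex_from_snp_panel(snp, sex_panel)$call), "male")
  expect_identical(as.character(sex_from_str(str_)$call), "female")
})

test_that("concordance table counts row-wise with no-calls excluded from %", {
  calls <- tibble::tibble(
    sample_id = sprintf("s%d", 1:10),
    platform = "snp_panel",
    call = factor(c("male", "male", "female", "female", "female", "no_call",
                    "female", "female", "male", "no_call"),
                  levels = c("male", "female", "no_call"))
  )
  ann <- tibble::tibble(
    sample_id = sprintf("s%d", 1:10),
    annotated_sex = c(rep("male", 6), rep("female", 3), "unknown")
  )
  tab <- sex_concordance(calls, ann)
  male_row <- tab[tab$annotated == "male", ]
  expect_identical(male_row$n_male, 2L)
  expect_identical(male_row$n_female, 3L)
  expect_identical(male_row$n_no_call, 1L)
  expect_equal(male_row$pct_female, 60)
  expect_identical(attr(tab, "n_unannotated"), 1L)
  # all-concordant and empty corners
  perfect <- sex_concordance(calls[3:5, ], ann[3:5, ] |>
                               dplyr::mutate(annotated_sex = "female"))
  expect_identical(perfect$n_male[perfect$annotated == "female"], 0L)
  empty <- sex_concordance(calls[0, ], ann[0, ])
  expect_identical(sum(empty$n_male, empty$n_female, empty$n_no_call), 0L)
})

test_that("PAR exclusion mask carries the PCDH11X/Y hg19 intervals", {
  regions <- par_exclusion_regions()
  y <- regions[regions$gene == "PCDH11Y", ]
  expect_identical(y$chromosome, "Y")
  expect_identical(y$start, 2988462L)
  expect_identical(y$end, 5587151L)
  x <- regions[regions$gene == "PCDH11X", ]
  expect_identical(c(x$start, x$end), c(88455396L, 92368901L))
})

test_that("chrY loss propagates to the SNP-panel miscall rate", {
  pop <- generate_population(synth_config(
    n_individuals = 150, chry_loss_rate = 0.3, male_fraction = 0.6,
    n_replicates = 0, n_synonymous = 0, seed = 21
  ))
  calls <- sex_from_snp_panel(pop$profiles, pop$panel)
  joined <- dplyr::inner_join(calls, pop$truth, by = "sample_id")
  males <- joined[joined$sex == "male", ]
  # exactly the Y-lost males are called female
  expect_identical(as.character(males$call[males$chry_lost]),
                   rep("female", sum(males$chry_lost)))
  expect_identical(as.character(males$call[!males$chry_lost]),
                   rep("male", sum(!males$chry_lost)))
  # with no Y loss every male is recovered
  pop0 <- generate_population(synth_config(
    n_individuals = 60, chry_loss_rate = 0, n_replicates = 0,
    n_synonymous = 0, seed = 22
  ))
  calls0 <- sex_from_snp_panel(pop0$profiles, pop0$panel)
  joined0 <- dplyr::inner_join(calls0, pop0$truth, by = "sample_id")
  expect_identical(as.character(joined0$call[joined0$sex == "male"]),
                   rep("male", sum(joined0$sex == "male")))
})
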