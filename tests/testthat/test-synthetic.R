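test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_individuals = 30, seed = 77)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  p3 <- generate_population(synth_config(n_individuals = 30, seed = 78))
  expect_false(identical(p1$profiles, p3$profiles))
})

test_that("config validation rejects impossible rates and sizes", {
  expect_error(synth_config(no_call_rate = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(male_fraction = -0.1), "\\[0, 1\\]")
  expect_error(synth_config(n_individuals = 4, n_replicates = 3,
                            n_synonymous = 3), "more planted")
  expect_error(synth_config(ancestry_freq_range = c(0, 0.9)), "inside")
})

test_that("genotype fractions follow Hardy-Weinberg at p = 0.5", {
  pop <- generate_population(synth_config(
    n_individuals = 600, n_replicates = 0, n_synonymous = 0,
    no_call_rate = 0, seed = 13
  ))
  fp <- pop$panel$marker_id[pop$panel$role == "autosomal_fingerprint"]
  g <- pop$profiles$genotype[pop$profiles$marker_id == fp[1]]
  n <- length(g)
  se <- 3 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(g == "A") - 0.25), se)
  expect_lt(abs(mean(g == "B") - 0.25), se)
  expect_lt(abs(mean(g == "A/B") - 0.5), 3 * sqrt(0.5 * 0.5 / n))
})

test_that("no-call rate lands near its target on autosomes only", {
  pop <- generate_population(synth_config(
    n_individuals = 200, no_call_rate = 0.05, n_replicates = 0,
    n_synonymous = 0, chry_loss_rate = 0, seed = 14
  ))
  auto <- autosomal_markers(pop$panel)
  g_auto <- pop$profiles$genotype[pop$profiles$marker_id %in% auto]
  emp <- mean(is.na(g_auto))
  expect_lt(abs(emp - 0.05), 3 * sqrt(0.05 * 0.95 / length(g_auto)))
  # allosomes carry no sprinkled no-calls: X always called
  x_markers <- pop$panel$marker_id[pop$panel$role == "chrX"]
  expect_false(anyNA(pop$profiles$genotype[pop$profiles$marker_id %in% x_markers]))
})

test_that("replicate derivation preserves co-called identity at zero error", {
  pop <- generate_population(synth_config(
    n_individuals = 5, n_replicates = 0, n_synonymous = 0, no_call_rate = 0,
    seed = 15
  ))
  # both rates zero: identical profile
  same <- derive_replicate(pop$profiles, "S0001", "rep0",
                           no_call_rate = 0, genotype_error_rate = 0, seed = 1)
  expect_identical(same$genotype, pop$profiles$genotype[
    pop$profiles$sample_id == "S0001"])
  # no-call only: dropped loci are excluded, the rest match exactly
  rep_ <- derive_replicate(pop$profiles, "S0001", "rep1",
                           no_call_rate = 0.1, genotype_error_rate = 0, seed = 2)
  combined <- dplyr::bind_rows(pop$profiles, rep_)
  ps <- tanabe_identity(combined, "S0001", "rep1", pop$panel)
  expect_equal(ps$score, 1)
  expect_lt(ps$n_loci, 90)
  # with genotype errors the score dips but stays near 1
  rep2 <- derive_replicate(pop$profiles, "S0001", "rep2",
                           no_call_rate = 0, genotype_error_rate = 0.05, seed = 3)
  ps2 <- tanabe_identity(dplyr::bind_rows(pop$profiles, rep2),
                         "S0001", "rep2", pop$panel)
  expect_lt(ps2$score, 1)
  expect_gt(ps2$score, 0.9)
})

test_that("LOH drift collapses heterozygous loci and lowers identity", {
  pop <- generate_population(synth_config(
    n_individuals = 5, n_replicates = 0, n_synonymous = 0, no_call_rate = 0,
    seed = 16
  ))
  parent <- pop$profiles[pop$profiles$sample_id == "S0002", ]
  # loh_rate 0: untouched
  syn0 <- derive_synonymous(pop$profiles, "S0002", "syn0", loh_rate = 0, seed = 1)
  expect_identical(syn0$genotype, parent$genotype)
  # loh_rate 1: every heterozygous locus collapses to one parental allele
  syn1 <- derive_synonymous(pop$profiles, "S0002", "syn1", loh_rate = 1, seed = 2)
  al_p <- genotype_alleles(parent$genotype)
  al_s <- genotype_alleles(syn1$genotype)
  expect_true(all(lengths(al_s[lengths(al_p) > 1]) == 1))
  expect_true(all(mapply(function(s, p) all(s %in% p), al_s, al_p)))
  # brute-force expectation for full LOH on a small panel: each het locus
  # contributes shared 1, totals 2 + 1; homozygous loci match exactly
  auto <- autosomal_markers(pop$panel)
  keep <- parent$marker_id %in% auto
  orc <- oracle_tanabe(
    setNames(genotype_alleles(parent$genotype[keep]), parent$marker_id[keep]),
    setNames(genotype_alleles(syn1$genotype[keep]), syn1$marker_id[keep])
  )
  ps <- tanabe_identity(dplyr::bind_rows(pop$profiles, syn1),
                        "S0002", "syn1", pop$panel)
  expect_equal(ps$score, orc$score)
  n_het <- sum(lengths(al_p[keep]) > 1)
  n_hom <- sum(lengths(al_p[keep]) == 1)
  expect_equal(orc$score,
               2 * (n_het + n_hom) / ((2 * n_het + n_hom) + (n_het + n_hom)))
  # moderate drift sits between unrelated and replicate levels
  syn <- derive_synonymous(pop$profiles, "S0002", "syn", loh_rate = 0.1, seed = 3)
  ps_mod <- tanabe_identity(dplyr::bind_rows(pop$profiles, syn),
                            "S0002", "syn", pop$panel)
  expect_gt(ps_mod$score, 0.9)
  expect_lte(ps_mod$score, 1)
})

test_that("MSI slippage degrades STR identity while SNPs are untouched", {
  strs <- generate_str_profiles(4, seed = 18)
  auto_loci <- powerplex_panel()$marker_id[powerplex_panel()$role == "str_autosomal"]
  # zero slippage: identical
  d0 <- derive_msi(strs$profiles, "STR0001", "msi0", slippage_rate = 0, seed = 1)
  expect_identical(d0$genotype,
                   strs$profiles$genotype[strs$profiles$sample_id == "STR0001"])
  # full slippage: every allele moves by one repeat
  d1 <- derive_msi(strs$profiles, "STR0001", "msi1", slippage_rate = 1, seed = 2)
  parent <- strs$profiles[strs$profiles$sample_id == "STR0001", ]
  for (mk in auto_loci) {
    pa <- as.numeric(genotype_alleles(parent$genotype[parent$marker_id == mk])[[1]])
    da <- as.numeric(genotype_alleles(d1$genotype[d1$marker_id == mk])[[1]])
    expect_true(all(da %in% c(pa - 1, pa + 1)), info = mk)
  }
  # amelogenin is never slipped
  expect_identical(d1$genotype[d1$marker_id == "AMEL"],
                   parent$genotype[parent$marker_id == "AMEL"])
  # moderate slippage: STR identity drops below the SNP identity (1.0)
  # of the same parent/derivative pair
  d <- derive_msi(strs$profiles, "STR0001", "msi", slippage_rate = 0.15, seed = 3)
  ps <- tanabe_identity(dplyr::bind_rows(strs$profiles, d),
                        "STR0001", "msi", markers = auto_loci)
  expect_lt(ps$score, 1)
})

test_that("aneuploid copy totals follow the requested law", {
  pop <- generate_population(synth_config(
    n_individuals = 12, n_replicates = 0, n_synonymous = 0, no_call_rate = 0,
    seed = 19
  ))
  cn <- generate_aneuploid_cn(pop$profiles, copies = 1:6, seed = 4)
  totals <- cn |>
    dplyr::summarise(total = sum(copies), .by = c(sample_id, marker_id))
  expect_true(all(totals$total %in% 1:6))
  n <- nrow(totals)
  for (v in 1:6) {
    expect_lt(abs(mean(totals$total == v) - 1 / 6),
              3 * sqrt((1 / 6) * (5 / 6) / n) + 1e-9)
  }
  # point mass at 4 on a homozygous locus puts all 4 copies on one allele
  hom <- tibble::tibble(sample_id = "s", marker_id = "m", genotype = "A")
  cn4 <- generate_aneuploid_cn(hom, copies = 4, seed = 5)
  expect_identical(cn4$copies, 4L)
  # diploid point mass reproduces the even split
  cn2 <- generate_aneuploid_cn(tibble::tibble(
    sample_id = "s", marker_id = "m", genotype = "A/B"), copies = 2, seed = 6)
  expect_identical(cn2$copies, c(1L, 1L))
})

test_that("planted classes separate: replicates and derivatives score above
           unrelated pairs", {
  pop <- generate_population(synth_config(n_individuals = 60, seed = 20))
  pr <- pairwise_identity(pop$profiles, pop$panel, pop$annotations)
  rep_scores <- pr$score[pr$pair_class == "replicate"]
  syn_scores <- pr$score[pr$pair_class == "synonymous"]
  unrel_scores <- pr$score[pr$pair_class == "unrelated"]
  expect_true(all(rep_scores > 0.9))
  expect_true(all(syn_scores > 0.9))
  expect_true(all(unrel_scores < 0.9))
})
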