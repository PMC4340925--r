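# Sex calling from three independent platforms.
#
# (i) SNP panel: 3 chromosome Y and 3 chromosome X assays. Y assays yield
#     no product in XX samples, so a Y "call" is evidence of Y material;
#     the triplicated design tolerates one failed assay.
# (ii) STR: the amelogenin locus, whose X and Y homologs differ in
#     amplicon length ({X} = female, {X,Y} = male).
# (iii) SNP array features: fraction of heterozygous genotypes on
#     chromosome X and mean pre-segmentation copy-number ratio on
#     chromosome Y (computed upstream with the pseudo-autosomal
#     PCDH11X/Y regions masked).
#
# All three platforms are deterministic rules on their own evidence; a
# sample can therefore be cross-checked across assays, which is how
# whole-chromosome Y loss in male-annotated cell lines was recognised as
# a biological signal rather than an assay artifact.

sex_levels <- c("male", "female", "no_call")

#' Sex call from the panel's allosome SNPs
#'
#' Calls `male` when at least 2 of the chromosome Y assays produce a
#' genotype, `female` when none do and at least 2 chromosome X assays
#' produce one, and `no_call` otherwise (exactly one Y call, or too few
#' valid assays to decide). Requiring two concordant Y assays keeps a
#' single spurious amplification from flipping a sex call.
#'
#' @param profiles Long profile tibble.
#' @param panel Marker-panel tibble with `chrX` and `chrY` roles.
#' @return A tibble: `sample_id`, `platform` (`"snp_panel"`), `call`,
#'   `n_y_called`, `n_y_total`, `n_x_called`, `n_x_total`.
#' @examples
#' pop <- generate_population(synth_config(
#'   n_individuals = 10, n_replicates = 2, n_synonymous = 2, seed = 1))
#' sex_from_snp_panel(pop$profiles, pop$panel)
#' @export
sex_from_snp_panel <- function(profiles, panel) {
  validate_panel(panel)
  x_markers <- panel$marker_id[panel$role == "chrX"]
  y_markers <- panel$marker_id[panel$role == "chrY"]
  if (length(x_markers) == 0 || length(y_markers) == 0) {
    abort("panel has no chrX/chrY markers")
  }
  samples <- unique(profiles$sample_id)
  calls <- profiles %>%
    filter(marker_id %in% c(x_markers, y_markers)) %>%
    mutate(on_y = marker_id %in% y_markers) %>%
    group_by(sample_id) %>%
    summarise(
      n_y_called = sum(on_y & !is.na(genotype)),
      n_x_called = sum(!on_y & !is.na(genotype)),
      .groups = "drop"
    )
  out <- tibble(sample_id = samples) %>%
    left_join(calls, by = "sample_id") %>%
    mutate(
      n_y_called = dplyr::coalesce(n_y_called, 0L),
      n_x_called = dplyr::coalesce(n_x_called, 0L),
      n_y_total = length(y_markers),
      n_x_total = length(x_markers),
      call = factor(dplyr::case_when(
        n_y_called >= 2 ~ "male",
        n_y_called == 0 & n_x_called >= 2 ~ "female",
        .default = "no_call"
      ), levels = sex_levels),
      platform = "snp_panel"
    )
  out %>% select(sample_id, platform, call, n_y_called, n_y_total,
                 n_x_called, n_x_total)
}

#' Sex call from the STR amelogenin locus
#'
#' `{X}` calls female, `{X,Y}` calls male; a no-call or a biologically
#' implausible `{Y}` (amelogenin X is never absent) gives `no_call`.
#'
#' @param profiles Long profile tibble containing an amelogenin row per
#'   sample.
#' @param amel_marker Marker id of the amelogenin locus (default
#'   `"AMEL"`).
#' @return A tibble: `sample_id`, `platform` (`"str"`), `call`,
#'   `amelogenin` (the observed genotype string).
#' @export
sex_from_str <- function(profiles, amel_marker = "AMEL") {
  rows <- profiles %>% filter(marker_id == amel_marker)
  if (nrow(rows) == 0) {
    abort(paste0("no '", amel_marker, "' rows in profiles"))
  }
  rows %>%
    mutate(
      call = factor(dplyr::case_when(
        genotype == "X" ~ "female",
        genotype == "X/Y" ~ "male",
        .default = "no_call"
      ), levels = sex_levels),
      platform = "str",
      amelogenin = genotype
    ) %>%
    select(sample_id, platform, call, amelogenin)
}

#' Sex call from SNP-array chromosome X/Y features
#'
#' A male call requires both a near-zero heterozygous fraction on
#' chromosome X (one X: almost no AB genotypes) and clear chromosome Y
#' copy-number signal; everything else is female. The default cutoffs are
#' `het_fraction_x <= 0.05` and `y_cn_ratio > 0.5` (ratio of 1 = genome
#' average). Samples in which only a minority of cells retain Y can fall
#' below the copy-number cutoff and be miscalled female — the known
#' false-negative mode of this rule.
#'
#' @param features Tibble with columns `sample_id`, `het_fraction_x`
#'   (fraction of called chromosome X SNPs with AB genotype) and
#'   `y_cn_ratio` (mean pre-segmentation chromosome Y copy-number ratio,
#'   computed with [par_exclusion_regions()] masked).
#' @param het_cutoff,y_cn_cutoff Decision cutoffs; defaults 0.05 and 0.5.
#' @return A tibble: `sample_id`, `platform` (`"array"`), `call`,
#'   `het_fraction_x`, `y_cn_ratio`. Missing features give `no_call`.
#' @examples
#' sex_from_array(tibble::tibble(
#'   sample_id = c("xy", "xx", "y_loss_mosaic"),
#'   het_fraction_x = c(0.02, 0.30, 0.02),
#'   y_cn_ratio = c(0.80, 0.05, 0.40)
#' ))
#' @export
sex_from_array <- function(features, het_cutoff = 0.05, y_cn_cutoff = 0.5) {
  stopifnot(all(c("sample_id", "het_fraction_x", "y_cn_ratio") %in% names(features)))
  features %>%
    mutate(
      call = factor(dplyr::case_when(
        is.na(het_fraction_x) | is.na(y_cn_ratio) ~ "no_call",
        het_fraction_x <= het_cutoff & y_cn_ratio > y_cn_cutoff ~ "male",
        .default = "female"
      ), levels = sex_levels),
      platform = "array"
    ) %>%
    select(sample_id, platform, call, het_fraction_x, y_cn_ratio)
}

#' Pseudo-autosomal exclusion regions for chromosome Y copy-number
#'
#' The hg19 intervals covering PCDH11Y and its cross-hybridizing X
#' homolog PCDH11X (the "PAR3" region), which show locally increased
#' apparent copy number in male samples and must be masked before
#' averaging chromosome Y copy-number ratios.
#'
#' @return A tibble: `chromosome`, `start`, `end`, `gene`.
#' @export
par_exclusion_regions <- function() {
  tibble(
    chromosome = c("Y", "X"),
    start = c(2988462L, 88455396L),
    end = c(5587151L, 92368901L),
    gene = c("PCDH11Y", "PCDH11X")
  )
}

#' Concordance of sex calls with annotation
#'
#' Cross-tabulates one platform's sex calls against annotated sex. Row
#' percentages are computed over decided calls only (no-calls are shown
#' but excluded from the denominators); samples lacking a male/female
#' annotation are excluded and counted separately.
#'
#' @param calls A sex-call tibble from one of the `sex_from_*()`
#'   functions.
#' @param annotations Sample-annotation tibble with `sample_id` and
#'   `annotated_sex`.
#' @return An object of class `cellauth_sex_concordance`: tibble with one
#'   row per annotated sex (`annotated`, `n_male`, `n_female`,
#'   `n_no_call`, `pct_male`, `pct_female`), with attributes `platform`
#'   and `n_unannotated`.
#' @examples
#' pop <- generate_population(synth_config(n_individuals = 50, seed = 1))
#' sex_concordance(sex_from_snp_panel(pop$profiles, pop$panel),
#'                 pop$annotations)
#' @export
sex_concordance <- function(calls, annotations) {
  platform <- unique(as.character(calls$platform))
  if (length(platform) > 1) {
    abort("calls mix platforms; concordance is per platform")
  }
  joined <- calls %>%
    left_join(annotations %>% select(sample_id, annotated_sex), by = "sample_id")
  n_unann <- sum(is.na(joined$annotated_sex) |
                   !joined$annotated_sex %in% c("male", "female"))
  joined <- joined %>% filter(annotated_sex %in% c("male", "female"))
  tab <- joined %>%
    count(annotated = annotated_sex, called = call) %>%
    tidyr::pivot_wider(names_from = called, values_from = n, values_fill = 0L)
  for (col in sex_levels) {
    if (!col %in% names(tab)) tab[[col]] <- 0L
  }
  out <- tibble(annotated = c("male", "female")) %>%
    left_join(tab, by = "annotated") %>%
    mutate(
      n_male = dplyr::coalesce(male, 0L),
      n_female = dplyr::coalesce(female, 0L),
      n_no_call = dplyr::coalesce(no_call, 0L),
      pct_male = ifelse(n_male + n_female > 0,
                        100 * n_male / (n_male + n_female), NA_real_),
      pct_female = ifelse(n_male + n_female > 0,
                          100 * n_female / (n_male + n_female), NA_real_)
    ) %>%
    select(annotated, n_male, n_female, n_no_call, pct_male, pct_female)
  structure(out, class = c("cellauth_sex_concordance", class(out)),
            platform = platform, n_unannotated = n_unann)
}

#' @export
print.cellauth_sex_concordance <- function(x, ...) {
  cat(sprintf("Sex-call concordance (%s platform)\n", attr(x, "platform")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  annotated %-6s: %d male (%s%%), %d female (%s%%), %d no-call\n",
      x$annotated[i], x$n_male[i],
      formatC(x$pct_male[i], format = "f", digits = 0),
      x$n_female[i],
      formatC(x$pct_female[i], format = "f", digits = 0),
      x$n_no_call[i]
    ))
  }
  if (attr(x, "n_unannotated") > 0) {
    cat(sprintf("  %d sample(s) without sex annotation excluded\n",
                attr(x, "n_unannotated")))
  }
  invisible(x)
}
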