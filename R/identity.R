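# Pairwise allele-sharing identity scoring.
#
# For each locus at which both samples have a called genotype, count the
# distinct alleles in each sample and the distinct alleles present in
# both; sum the three counts over loci and score
#   identity = 2 * shared / (total_a + total_b).
# The score is 1 iff the two profiles carry identical allele sets at every
# co-called locus and 0 iff they share no allele anywhere. Nothing assumes
# diploidy or biallelic markers, so SNP and STR profiles (including >2
# alleles per locus in aneuploid lines) score through the same code path.

pair_classes <- c("replicate", "synonymous", "unrelated", "unannotated")

# shared/total sums for all pairs, from an encoding. Returns list of
# matrices [n_pairs x m]: shared, total (0 where either side is no-call),
# plus index vectors ii, jj.
pair_count_matrices <- function(enc) {
  n <- length(enc$samples)
  m <- length(enc$markers)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  ii <- idx[, 1]
  jj <- idx[, 2]
  shared <- matrix(0L, length(ii), m)
  total <- matrix(0L, length(ii), m)
  for (k in seq_len(m)) {
    a <- enc$masks[ii, k]
    b <- enc$masks[jj, k]
    called <- a > 0L & b > 0L
    shared[, k] <- popcount(bitwAnd(a, b)) * called
    total[, k] <- (enc$counts[ii, k] + enc$counts[jj, k]) * called
  }
  list(shared = shared, total = total, ii = ii, jj = jj)
}

#' Tanabe identity score for one pair of samples
#'
#' Computes the allele-sharing identity score
#' `2 * shared / (total_a + total_b)` between two samples, summing
#' distinct-allele counts over every marker at which neither sample is a
#' no-call. By default scoring uses the panel's autosomal markers only;
#' sex markers are excluded so that same-sex samples do not look related.
#'
#' @param profiles Long profile tibble containing both samples.
#' @param sample_a,sample_b Sample ids to compare.
#' @param panel Marker-panel tibble; used to pick the default (autosomal)
#'   marker set.
#' @param markers Optional character vector of marker ids to score over,
#'   overriding the autosomal default.
#' @return A one-row tibble: `sample_a`, `sample_b`, `n_loci` (co-called),
#'   `shared`, `total_a`, `total_b`, `score`.
#' @details A pair with no co-called locus has an undefined score and is
#'   an error here (see [pairwise_identity()] for the flagged-record
#'   variant); an undefined score is deliberately distinct from 0, which
#'   asserts that no allele is shared.
#' @examples
#' profs <- tibble::tribble(
#'   ~sample_id, ~marker_id, ~genotype,
#'   "s1", "m1", "A",   "s1", "m2", "A/B",
#'   "s2", "m1", "A/B", "s2", "m2", "A/B"
#' )
#' tanabe_identity(profs, "s1", "s2", markers = c("m1", "m2"))  # 6/7
#' @export
tanabe_identity <- function(profiles, sample_a, sample_b, panel = NULL,
                            markers = NULL) {
  markers <- resolve_markers(profiles, panel, markers)
  enc <- encode_profiles(profiles, markers, samples = c(sample_a, sample_b))
  a <- enc$masks[1, ]
  b <- enc$masks[2, ]
  called <- a > 0L & b > 0L
  if (!any(called)) {
    abort("no co-called loci between the two samples; identity score is undefined",
          class = "cellauth_undefined_score")
  }
  sh <- sum(popcount(bitwAnd(a, b))[called])
  ta <- sum(enc$counts[1, called])
  tb <- sum(enc$counts[2, called])
  tibble(
    sample_a = sample_a, sample_b = sample_b,
    n_loci = sum(called), shared = sh, total_a = ta, total_b = tb,
    score = 2 * sh / (ta + tb)
  )
}

resolve_markers <- function(profiles, panel, markers) {
  if (!is.null(markers)) {
    if (length(markers) == 0) abort("markers must be nonempty")
    return(markers)
  }
  if (!is.null(panel)) {
    return(autosomal_markers(panel))
  }
  unique(profiles$marker_id)
}

#' All-pairs identity score matrix
#'
#' Scores every unordered pair of samples (`n * (n - 1) / 2` pairs) and,
#' when annotations are supplied, labels each pair by its expected
#' relationship: `replicate` (same `replicate_group`), else `synonymous`
#' (same `synonym_group`, e.g. lines derived from one patient), else
#' `unrelated` when both samples are annotated, else `unannotated`.
#'
#' @inheritParams tanabe_identity
#' @param annotations Optional sample-annotation tibble (columns
#'   `sample_id`, `replicate_group`, `synonym_group`).
#' @return A tibble with one row per pair: `sample_a`, `sample_b`,
#'   `pair_class`, `n_loci`, `shared`, `total_a`, `total_b`, `score`.
#'   Pairs with no co-called locus get `score = NA` (undefined, flagged
#'   rather than dropped).
#' @examples
#' pop <- generate_population(synth_config(
#'   n_individuals = 6, n_replicates = 1, n_synonymous = 1, seed = 1))
#' pairwise_identity(pop$profiles, pop$panel, pop$annotations)
#' @export
pairwise_identity <- function(profiles, panel = NULL, annotations = NULL,
                              markers = NULL) {
  markers <- resolve_markers(profiles, panel, markers)
  samples <- unique(profiles$sample_id)
  if (length(samples) < 2) {
    abort("need at least two samples")
  }
  enc <- encode_profiles(profiles, markers, samples = samples)
  pcm <- pair_count_matrices(enc)
  sh <- as.integer(rowSums(pcm$shared))
  n_loci <- as.integer(rowSums(pcm$total > 0L))
  # per-side totals over co-called loci
  ta <- integer(length(pcm$ii))
  tb <- integer(length(pcm$ii))
  for (k in seq_along(markers)) {
    called <- pcm$total[, k] > 0L
    ta <- ta + enc$counts[pcm$ii, k] * called
    tb <- tb + enc$counts[pcm$jj, k] * called
  }
  out <- tibble(
    sample_a = samples[pcm$ii],
    sample_b = samples[pcm$jj],
    n_loci = n_loci,
    shared = sh,
    total_a = ta,
    total_b = tb,
    score = ifelse(ta + tb > 0, 2 * sh / (ta + tb), NA_real_)
  )
  out$pair_class <- classify_pair_relation(out$sample_a, out$sample_b, annotations)
  out %>% select(sample_a, sample_b, pair_class, dplyr::everything())
}

# replicate > synonymous > unrelated precedence; unannotated when either
# sample is missing from the annotations.
classify_pair_relation <- function(a, b, annotations) {
  if (is.null(annotations)) {
    return(factor(rep("unannotated", length(a)), levels = pair_classes))
  }
  ia <- match(a, annotations$sample_id)
  ib <- match(b, annotations$sample_id)
  rg_a <- annotations$replicate_group[ia]
  rg_b <- annotations$replicate_group[ib]
  sg_a <- annotations$synonym_group[ia]
  sg_b <- annotations$synonym_group[ib]
  cls <- dplyr::case_when(
    is.na(ia) | is.na(ib) ~ "unannotated",
    !is.na(rg_a) & !is.na(rg_b) & rg_a == rg_b ~ "replicate",
    !is.na(sg_a) & !is.na(sg_b) & sg_a == sg_b ~ "synonymous",
    .default = "unrelated"
  )
  factor(cls, levels = pair_classes)
}

#' Discriminatory power of random marker subsets
#'
#' Estimates how the spread of unrelated-pair identity scores grows as the
#' marker panel shrinks. For each of `n_draws` seeded draws, `k` autosomal
#' markers are sampled without replacement, all unrelated pairs are
#' rescored over the subset, and the standard deviation of their scores is
#' recorded. A tighter unrelated-score distribution means unrelated
#' samples are less likely to cross the identity threshold by chance, so
#' smaller SD = more discriminatory power.
#'
#' @inheritParams pairwise_identity
#' @param k Subset size (number of markers); must be at least 2.
#' @param n_draws Number of random subsets to draw (default 100).
#' @param seed Integer seed for the subset draws.
#' @return An object of class `cellauth_subset_power`: a tibble with one
#'   row per draw (`draw`, `k`, `mean_score`, `sd_score`) carrying
#'   attributes `k`, `n_draws`, `seed`, `full_sd` (unrelated SD over all
#'   autosomal markers), `pooled_sd` (SD of all draws' scores pooled) and
#'   `n_pairs`. `glance()` returns the summary as a one-row tibble.
#' @examples
#' pop <- generate_population(synth_config(n_individuals = 30, seed = 1))
#' sp <- subset_power(pop$profiles, pop$panel, pop$annotations,
#'                    k = 24, n_draws = 20, seed = 7)
#' glance(sp)
#' @export
subset_power <- function(profiles, panel, annotations = NULL, k,
                         n_draws = 100, seed = 1L, markers = NULL) {
  markers <- resolve_markers(profiles, panel, markers)
  m <- length(markers)
  if (k > m) abort("k exceeds the number of available autosomal markers")
  if (k < 2) abort("k must be at least 2")
  if (n_draws < 1) abort("n_draws must be at least 1")

  samples <- unique(profiles$sample_id)
  enc <- encode_profiles(profiles, markers, samples = samples)
  pcm <- pair_count_matrices(enc)
  cls <- classify_pair_relation(samples[pcm$ii], samples[pcm$jj], annotations)
  keep <- if (is.null(annotations)) rep(TRUE, length(pcm$ii)) else cls == "unrelated"
  shared <- pcm$shared[keep, , drop = FALSE]
  total <- pcm$total[keep, , drop = FALSE]

  full_scores <- 2 * rowSums(shared) / rowSums(total)
  full_scores <- full_scores[is.finite(full_scores)]
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      s <- sample.int(m, k)
      sc <- 2 * rowSums(shared[, s, drop = FALSE]) / rowSums(total[, s, drop = FALSE])
      sc[is.finite(sc)]
    })
  })
  per_draw <- tibble(
    draw = seq_len(n_draws),
    k = k,
    mean_score = vapply(draws, mean, numeric(1)),
    sd_score = vapply(draws, sd, numeric(1))
  )
  structure(
    per_draw,
    class = c("cellauth_subset_power", class(per_draw)),
    k = k, n_draws = n_draws, seed = seed,
    full_sd = sd(full_scores),
    pooled_sd = sd(unlist(draws, use.names = FALSE)),
    n_pairs = sum(keep)
  )
}

#' @exportS3Method generics::glance
glance.cellauth_subset_power <- function(x, ...) {
  tibble(
    k = attr(x, "k"),
    n_draws = attr(x, "n_draws"),
    seed = attr(x, "seed"),
    n_pairs = attr(x, "n_pairs"),
    mean_sd = mean(x$sd_score),
    sd_of_sd = sd(x$sd_score),
    pooled_sd = attr(x, "pooled_sd"),
    full_panel_sd = attr(x, "full_sd")
  )
}

#' @exportS3Method generics::tidy
tidy.cellauth_subset_power <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
print.cellauth_subset_power <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Marker-subset power analysis: k = %d, %d draws (seed %d), %d unrelated pairs\n",
    g$k, g$n_draws, g$seed, g$n_pairs
  ))
  cat(sprintf("  mean subset SD %.4f (pooled %.4f); full-panel SD %.4f\n",
              g$mean_sd, g$pooled_sd, g$full_panel_sd))
  invisible(x)
}
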