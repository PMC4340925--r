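# In-silico cross-contamination as copy-number weighted genotype mixtures.
#
# A mixed sample is modeled per locus: each component contributes its
# alleles in proportion to (mixing fraction x per-allele copy number),
# and an allele is genotyped in the mixture when its relative abundance
#   sum_c f_c * copies_c(allele) / sum_c f_c * total_copies_c
# reaches the detection threshold tau. Contamination is then detected
# exactly as authentication failure: the mixture's identity score against
# its expected reference falls below the identity threshold (default
# 0.90). Because abundance is copy-number weighted, a high-copy
# contaminant crosses tau at a lower mixing fraction than a low-copy one,
# which is why reciprocal mixes of aneuploid lines are not detected with
# equal sensitivity.

# Per-allele copy weights for one sample at the scored markers. `cn` is a
# tibble (sample_id, marker_id, allele, copies); loci absent from it
# default to an even split of 2 copies (diploid) across the called
# alleles.
cn_weights <- function(profile_rows, cn, id) {
  al <- genotype_alleles(profile_rows$genotype)
  out <- tibble(
    marker_id = rep(profile_rows$marker_id, lengths(al)),
    allele = unlist(al, use.names = FALSE),
    copies = NA_real_
  )
  if (!is.null(cn)) {
    cn_id <- cn[cn$sample_id == id, c("marker_id", "allele", "copies")]
    if (nrow(cn_id) > 0) {
      out <- out %>%
        left_join(cn_id, by = c("marker_id", "allele"), suffix = c("", ".cn")) %>%
        mutate(copies = .data$copies.cn) %>%
        select(marker_id, allele, copies)
    }
  }
  out %>%
    group_by(marker_id) %>%
    mutate(copies = ifelse(is.na(copies), 2 / n(), copies)) %>%
    ungroup()
}

#' Simulate a cross-contaminated genotype profile
#'
#' Builds the deterministic genotype profile of a DNA mixture. Component
#' fractions must sum to 1; per-allele copy numbers (optional `cn` table)
#' weight each component's contribution, with diploid (2 copies split
#' evenly across called alleles) as the default. At each marker the
#' called allele set is every allele whose relative abundance reaches
#' `tau`; a marker at which every contributing component is a no-call is
#' a no-call in the mixture.
#'
#' @param profiles Long profile tibble containing all component samples.
#' @param fractions Named numeric vector of mixing fractions (names are
#'   sample ids present in `profiles`); must sum to 1 within 1e-9.
#' @param cn Optional copy-number tibble (`sample_id`, `marker_id`,
#'   `allele`, `copies`).
#' @param tau Allele-detection threshold in `(0, 0.5)`: the minimum
#'   relative abundance at which an allele is genotyped. Default 0.04,
#'   chosen so that an even diploid mixture reproduces the observed
#'   wet-lab behaviour (a 5% contaminant's homozygous alleles are seen, a
#'   1% contaminant's are not). Assay chemistry sensitivity is not a
#'   published constant, so this is exposed as a knob.
#' @param sample_id Sample id given to the mixture profile.
#' @return A long profile tibble for the mixture (one row per marker seen
#'   in any component).
#' @examples
#' profs <- dplyr::bind_rows(
#'   tibble::tibble(sample_id = "host", marker_id = c("m1", "m2"),
#'                  genotype = c("A", "A/B")),
#'   tibble::tibble(sample_id = "cont", marker_id = c("m1", "m2"),
#'                  genotype = c("B", "A/B"))
#' )
#' simulate_mixture(profs, c(host = 0.95, cont = 0.05))
#' @export
simulate_mixture <- function(profiles, fractions, cn = NULL, tau = 0.04,
                             sample_id = "mixture") {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    abort("fractions must be named by sample id")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("mixing fractions must sum to 1")
  }
  if (!(tau > 0 && tau < 0.5)) {
    abort("tau must be in (0, 0.5)")
  }
  ids <- names(fractions)
  missing <- setdiff(ids, unique(profiles$sample_id))
  if (length(missing) > 0) {
    abort(paste0("components not in profiles: ", paste(missing, collapse = ", ")))
  }
  mix_id <- sample_id

  contrib <- purrr::map(ids, function(id) {
    rows <- profiles[profiles$sample_id == id, ]
    called <- rows[!is.na(rows$genotype), ]
    w <- cn_weights(called, cn, id)
    w$weight <- w$copies * fractions[[id]]
    w
  }) %>% bind_rows()

  markers <- unique(profiles$marker_id[profiles$sample_id %in% ids])
  if (nrow(contrib) == 0) {
    return(tibble(sample_id = mix_id, marker_id = markers,
                  genotype = NA_character_))
  }
  denom <- contrib %>%
    group_by(marker_id) %>%
    summarise(total = sum(weight), .groups = "drop")
  called_set <- contrib %>%
    group_by(marker_id, allele) %>%
    summarise(weight = sum(weight), .groups = "drop") %>%
    left_join(denom, by = "marker_id") %>%
    mutate(abundance = ifelse(total > 0, weight / total, 0)) %>%
    filter(abundance >= tau - 1e-12) %>%
    group_by(marker_id) %>%
    summarise(genotype = genotype(allele), .groups = "drop")

  tibble(marker_id = markers) %>%
    left_join(called_set, by = "marker_id") %>%
    mutate(sample_id = mix_id) %>%
    select(sample_id, marker_id, genotype)
}

#' Test an observed profile against its expected reference
#'
#' Declares contamination (or misidentification) when the identity score
#' between the observed profile and its expected reference falls below
#' the authentication threshold — the same 0.90 cutoff used to call two
#' samples identical.
#'
#' @param observed,reference Long profile tibbles (one sample each).
#' @param markers Optional marker subset; defaults to all shared markers.
#' @param threshold Identity threshold; default 0.90.
#' @return A one-row tibble: `observed`, `reference`, `score`,
#'   `contaminated` (logical; `NA` when the score is undefined),
#'   `status` (`"clean"`, `"contaminated"` or `"indeterminate"`).
#' @export
contamination_scan <- function(observed, reference, markers = NULL,
                               threshold = 0.9) {
  obs_id <- unique(observed$sample_id)
  ref_id <- unique(reference$sample_id)
  stopifnot(length(obs_id) == 1, length(ref_id) == 1)
  if (obs_id == ref_id) {
    reference <- reference %>% mutate(sample_id = paste0(ref_id, ".ref"))
    ref_id <- paste0(ref_id, ".ref")
  }
  combined <- bind_rows(observed, reference)
  ps <- tryCatch(
    tanabe_identity(combined, obs_id, ref_id, markers = markers %||%
                      intersect(unique(observed$marker_id),
                                unique(reference$marker_id))),
    cellauth_undefined_score = function(e) NULL
  )
  if (is.null(ps)) {
    return(tibble(observed = obs_id, reference = ref_id, score = NA_real_,
                  contaminated = NA, status = "indeterminate"))
  }
  tibble(
    observed = obs_id, reference = ref_id, score = ps$score,
    contaminated = ps$score < threshold,
    status = ifelse(ps$score < threshold, "contaminated", "clean")
  )
}

#' Contamination sensitivity curve over a mixing-ratio ladder
#'
#' Sweeps the contaminant fraction over the experimental mixing ladder
#' (100:0, 99:1, 98:2, 95:5, 90:10, 50:50 and the reciprocals), simulates
#' each mixture of `host` and `contaminant`, and scores it against both
#' parents. A fraction is "detected in" a parent when the mixture is no
#' longer identical to that parent (identity < `threshold`). Copy-number
#' tables for either side let the curve reproduce the asymmetric
#' detection of reciprocal mixes of aneuploid lines.
#'
#' @param profiles Long profile tibble containing both parents.
#' @param host,contaminant Sample ids of the two parents; `fraction` is
#'   the contaminant's share of the mixture.
#' @param cn Optional copy-number tibble covering either or both parents.
#' @param fractions Contaminant fractions to sweep (default the full
#'   reciprocal ladder `0, 0.01, 0.02, 0.05, 0.1, 0.5, 0.9, 0.95, 0.98,
#'   0.99, 1`).
#' @param tau Allele-detection threshold, see [simulate_mixture()].
#' @param threshold Identity threshold; default 0.90.
#' @param markers Optional marker subset for scoring.
#' @return An object of class `cellauth_sensitivity`: tibble with one row
#'   per fraction (`fraction`, `identity_vs_host`, `identity_vs_contaminant`,
#'   `detected_in_host`, `detected_in_contaminant`), with attributes
#'   `host`, `contaminant`, `tau`, `threshold`. `detected_in_host` means a
#'   lab expecting the host would notice the contamination at that
#'   fraction.
#' @examples
#' profs <- dplyr::bind_rows(
#'   tibble::tibble(sample_id = "a", marker_id = paste0("m", 1:4),
#'                  genotype = "A"),
#'   tibble::tibble(sample_id = "b", marker_id = paste0("m", 1:4),
#'                  genotype = "B")
#' )
#' sensitivity_curve(profs, "a", "b")
#' @export
sensitivity_curve <- function(profiles, host, contaminant, cn = NULL,
                              fractions = c(0, 0.01, 0.02, 0.05, 0.1, 0.5,
                                            0.9, 0.95, 0.98, 0.99, 1),
                              tau = 0.04, threshold = 0.9, markers = NULL) {
  if (any(fractions < 0 | fractions > 1)) {
    abort("fractions must be in [0, 1]")
  }
  host_rows <- profiles %>% filter(sample_id == host)
  cont_rows <- profiles %>% filter(sample_id == contaminant)
  rows <- purrr::map(fractions, function(f) {
    mix <- if (f == 0) {
      host_rows %>% mutate(sample_id = "mixture")
    } else if (f == 1) {
      cont_rows %>% mutate(sample_id = "mixture")
    } else {
      simulate_mixture(profiles,
                       setNames(c(1 - f, f), c(host, contaminant)),
                       cn = cn, tau = tau)
    }
    sa <- contamination_scan(mix, host_rows, markers = markers,
                             threshold = threshold)
    sb <- contamination_scan(mix, cont_rows, markers = markers,
                             threshold = threshold)
    tibble(
      fraction = f,
      identity_vs_host = sa$score,
      identity_vs_contaminant = sb$score,
      detected_in_host = sa$contaminated,
      detected_in_contaminant = sb$contaminated
    )
  }) %>% bind_rows()
  structure(rows, class = c("cellauth_sensitivity", class(rows)),
            host = host, contaminant = contaminant, tau = tau,
            threshold = threshold)
}

#' Smallest contaminant fraction flagged by the identity rule
#'
#' @param curve A `cellauth_sensitivity` from [sensitivity_curve()].
#' @param direction `"host"`: smallest fraction at which the mixture is no
#'   longer identical to the host (the contaminant is noticed);
#'   `"contaminant"`: the reciprocal direction, measured as the smallest
#'   host share `1 - fraction` flagged against the contaminant.
#' @return A single fraction, or `NA` if never detected.
#' @export
min_detected_fraction <- function(curve, direction = c("host", "contaminant")) {
  direction <- arg_match(direction)
  if (direction == "host") {
    det <- curve$fraction[!is.na(curve$detected_in_host) &
                            curve$detected_in_host & curve$fraction > 0]
    if (length(det) == 0) NA_real_ else min(det)
  } else {
    det <- 1 - curve$fraction[!is.na(curve$detected_in_contaminant) &
                                curve$detected_in_contaminant & curve$fraction < 1]
    if (length(det) == 0) NA_real_ else min(det)
  }
}
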