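# Gaussian reference distributions and relatedness p-values.
#
# Identity scores within one pair class (unrelated, synonymous, replicate)
# are approximately Gaussian: each score is a ratio of allele counts
# summed over ~90 independent loci. A reference distribution is the
# sample mean and SD of the class after iterative outlier trimming
# (misannotated pairs would otherwise corrupt the fit). A pair's
# relatedness evidence is then a normal tail probability: the upper tail
# under the unrelated reference answers "how often would two unrelated
# samples score at least this high?".

#' Fit a Gaussian reference distribution to a pair class
#'
#' Takes a pairwise score table (from [pairwise_identity()]), keeps the
#' requested class, iteratively removes outliers (robust z-score
#' |score - median| / (1.4826 MAD) above `outlier_z`, refit, repeat to
#' convergence) and records the mean and
#' sample (n-1) standard deviation of the remaining scores. Excluded
#' pairs are always reported, never silently dropped.
#'
#' @param pairs Pairwise score tibble with columns `sample_a`, `sample_b`,
#'   `pair_class`, `score`.
#' @param pair_class Which class to fit (default `"unrelated"`).
#' @param outlier_z Trimming threshold in SD units; `Inf` disables
#'   trimming. Default 4.
#' @param tail Which tail carries relatedness evidence under this
#'   reference: `"upper"` for the unrelated reference (high score =
#'   related), `"lower"` for a related-class reference (low score =
#'   divergent).
#' @return An object of class `cellauth_ref`: list with `pair_class`,
#'   `mean`, `sd`, `n_pairs` (included), `excluded` (tibble of trimmed
#'   pairs with their z under the final fit), `tail`, `degenerate`
#'   (`TRUE` when `sd == 0`). `tidy()` returns the excluded pairs,
#'   `glance()` the fit as a one-row tibble.
#' @examples
#' pairs <- tibble::tibble(
#'   sample_a = "a", sample_b = letters[2:11], pair_class = "unrelated",
#'   score = c(0.70, 0.72, 0.74, 0.75, 0.76, 0.77, 0.78, 0.79, 0.80, 0.81)
#' )
#' fit_reference(pairs, "unrelated")
#' @export
fit_reference <- function(pairs, pair_class = "unrelated", outlier_z = 4,
                          tail = NULL) {
  cls <- pair_class
  if (is.null(tail)) {
    tail <- if (cls == "unrelated") "upper" else "lower"
  }
  tail <- arg_match(tail, c("upper", "lower"))
  keep <- pairs[!is.na(pairs$score) & as.character(pairs$pair_class) == cls, ]
  if (nrow(keep) < 2) {
    abort(paste0("need at least 2 scored pairs of class '", cls, "' to fit"))
  }
  # Outlier detection uses a robust centre/scale (median and scaled MAD)
  # so that a gross outlier cannot mask itself by inflating the SD it is
  # judged against; the reported fit is the plain mean/SD of what remains.
  included <- rep(TRUE, nrow(keep))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 100L) break
    centre <- stats::median(keep$score[included])
    scale <- stats::mad(keep$score[included])
    if (!is.finite(scale) || scale == 0) {
      scale <- sd(keep$score[included])
    }
    if (!is.finite(scale) || scale == 0) break
    z <- abs(keep$score - centre) / scale
    new_included <- z <= outlier_z
    if (identical(new_included, included)) break
    if (sum(new_included) < 2) break
    included <- new_included
  }
  mu <- mean(keep$score[included])
  sdev <- sd(keep$score[included])
  degenerate <- !is.finite(sdev) || sdev == 0
  if (degenerate) {
    sdev <- 0
    warn(paste0("degenerate reference for class '", cls, "': all scores equal"))
  }
  excluded <- keep[!included, c("sample_a", "sample_b", "score")]
  excluded$z <- if (degenerate) NA_real_ else (excluded$score - mu) / sdev
  structure(
    list(pair_class = cls, mean = mu, sd = sdev,
         n_pairs = sum(included), excluded = tibble::as_tibble(excluded),
         tail = tail, degenerate = degenerate),
    class = "cellauth_ref"
  )
}

#' @export
print.cellauth_ref <- function(x, ...) {
  cat(sprintf(
    "Gaussian reference (%s pairs, %s tail): mean %.4f, sd %.4f, n %d%s\n",
    x$pair_class, x$tail, x$mean, x$sd, x$n_pairs,
    if (x$degenerate) " [degenerate]" else ""
  ))
  if (nrow(x$excluded) > 0) {
    cat(sprintf("  %d outlier pair(s) excluded from the fit\n", nrow(x$excluded)))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cellauth_ref <- function(x, ...) {
  tibble(
    pair_class = x$pair_class, mean = x$mean, sd = x$sd,
    n_pairs = x$n_pairs, n_excluded = nrow(x$excluded),
    tail = x$tail, degenerate = x$degenerate
  )
}

#' @exportS3Method generics::tidy
tidy.cellauth_ref <- function(x, ...) {
  x$excluded
}

#' Normal tail probability of an identity score
#'
#' Evaluates the reference's tail probability at `score`: for an upper
#' tail, `1 - pnorm((score - mean) / sd)` (the probability that a pair of
#' the reference class scores at least this high); for a lower tail the
#' complementary direction. A degenerate (sd = 0) reference yields a step
#' function (0/1, or 0.5 exactly at the mean) with a warning.
#'
#' @param score Numeric vector of identity scores.
#' @param ref A `cellauth_ref` from [fit_reference()].
#' @return Numeric vector of tail probabilities in `[0, 1]`.
#' @examples
#' ref <- structure(
#'   list(mean = 0.75, sd = 0.05, tail = "upper", degenerate = FALSE),
#'   class = "cellauth_ref"
#' )
#' relatedness_pvalue(c(0.75, 0.95), ref)
#' @export
relatedness_pvalue <- function(score, ref) {
  stopifnot(inherits(ref, "cellauth_ref"))
  if (ref$degenerate) {
    warn("degenerate reference distribution: returning a step function")
    # point mass at the mean: P(X >= s) is 1 below it, 0 above it
    upper <- as.numeric(score < ref$mean)
    upper[score == ref$mean] <- 0.5
    return(if (ref$tail == "upper") upper else 1 - upper)
  }
  z <- (score - ref$mean) / ref$sd
  if (ref$tail == "upper") {
    pnorm(z, lower.tail = FALSE)
  } else {
    pnorm(z)
  }
}

#' Classify pairs at an identity threshold with relatedness p-values
#'
#' Applies the authentication decision rule to a pairwise score table:
#' a pair is called identical when `score >= threshold` (default 0.90).
#' Each pair is annotated with the upper-tail probability under the
#' unrelated reference (`p_unrelated`: how often an unrelated pair scores
#' this high — small values flag relatedness) and, when supplied, the
#' lower-tail probability under the synonymous reference
#' (`p_synonymous`: how often a genuinely related pair scores this low —
#' small values flag divergence). Discordance flags mark pairs whose
#' annotation disagrees with the call: annotated-unrelated pairs that
#' score identical ("identical, not previously known") and
#' annotated-related pairs that do not.
#'
#' @param pairs Pairwise score tibble from [pairwise_identity()].
#' @param refs Named list of `cellauth_ref` objects; recognised names are
#'   `"unrelated"` and `"synonymous"`. Missing references simply omit the
#'   corresponding p-value column content (NA).
#' @param threshold Identity threshold in `(0, 1]`; default 0.90.
#' @return The input tibble plus columns `p_unrelated`, `p_synonymous`,
#'   `is_identical` and `flag` (NA when concordant).
#' @examples
#' pop <- generate_population(synth_config(n_individuals = 20, seed = 1))
#' pairs <- pairwise_identity(pop$profiles, pop$panel, pop$annotations)
#' refs <- list(unrelated = fit_reference(pairs, "unrelated"))
#' calls <- classify_pairs(pairs, refs)
#' dplyr::filter(calls, !is.na(flag))
#' @export
classify_pairs <- function(pairs, refs = list(), threshold = 0.9) {
  if (!(threshold > 0 && threshold <= 1)) {
    abort("threshold must be in (0, 1]")
  }
  out <- pairs
  out$p_unrelated <- if (!is.null(refs$unrelated)) {
    relatedness_pvalue(out$score, refs$unrelated)
  } else {
    NA_real_
  }
  out$p_synonymous <- if (!is.null(refs$synonymous)) {
    relatedness_pvalue(out$score, refs$synonymous)
  } else {
    NA_real_
  }
  out$is_identical <- !is.na(out$score) & out$score >= threshold
  cls <- as.character(out$pair_class)
  out$flag <- dplyr::case_when(
    is.na(out$score) ~ "undefined score (no co-called loci)",
    out$is_identical & cls %in% c("unrelated", "unannotated") ~
      "identical, not previously known",
    !out$is_identical & cls %in% c("replicate", "synonymous") ~
      "annotated related but profiles differ",
    .default = NA_character_
  )
  out
}
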