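# Reading and writing sample-by-marker profile tables.
#
# The on-disk layout follows published supplementary genotyping tables:
# one row per sample, annotation columns first (sample_id plus optional
# cell_line_name, clid, sex, replicate_type, replicate_group,
# synonym_group and any number of free-form columns), then one column per
# panel marker holding the genotype token.

ANNOTATION_COLS <- c(
  "sample_id", "cell_line_name", "clid", "sex", "replicate_type",
  "replicate_group", "synonym_group"
)

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) {
    return(arg_match(format, c("csv", "tsv", "xlsx")))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv", "xlsx")) ext else "csv"
}

read_table_raw <- function(path, format) {
  switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = readr::col_character())),
    tsv = readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character())),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("reading xlsx requires the readxl package")
      }
      readxl::read_excel(path, col_types = "text")
    }
  )
}

#' Read a sample-by-marker profile table
#'
#' Parses a wide genotype table (one row per sample, one column per panel
#' marker) into a long profile tibble plus a sample-annotation tibble.
#' Genotype tokens are normalised into canonical genotype strings: SNP
#' tokens such as `"AA"` collapse to the distinct-allele set `"A"`, STR
#' tokens such as `"9,9.3"` become `"9/9.3"`, and any of the no-call
#' spellings `"No Call"`, `"NC"`, `"NoCall"`, `""` or an em dash (case
#' insensitive) become `NA`.
#'
#' Columns whose names are not panel marker ids are treated as sample
#' annotations; `sample_id` is required and must be unique. Recognised
#' annotation columns are `cell_line_name`, `clid`, `sex`
#' (male/female/unknown), `replicate_type` (`TR`, `BR` or blank),
#' `replicate_group` and `synonym_group`; other columns are carried
#' through untouched.
#'
#' @param path Path to a CSV, TSV or XLSX file.
#' @param panel Marker-panel tibble; every panel marker must appear as a
#'   column.
#' @param format `"csv"`, `"tsv"` or `"xlsx"`; inferred from the file
#'   extension by default.
#' @param strict If `TRUE` (default) an unparseable genotype token is an
#'   error naming the offending row and column; if `FALSE` such tokens
#'   become no-calls and are reported in the `parse_errors` attribute of
#'   the returned profiles.
#' @return A list with elements `profiles` (tibble: `sample_id`,
#'   `marker_id`, `genotype`; one row per sample x panel marker, samples
#'   in file order, markers in panel order) and `annotations` (tibble, one
#'   row per sample).
#' @seealso [write_profile_table()], [validate_profiles()]
#' @export
read_profile_table <- function(path, panel, format = NULL, strict = TRUE) {
  validate_panel(panel)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  format <- infer_format(path, format)
  raw <- read_table_raw(path, format)
  names(raw)[tolower(names(raw)) %in% ANNOTATION_COLS] <-
    tolower(names(raw)[tolower(names(raw)) %in% ANNOTATION_COLS])

  missing_markers <- setdiff(panel$marker_id, names(raw))
  if (length(missing_markers) > 0) {
    abort(paste0(
      "profile table does not match panel; missing marker column(s): ",
      paste(missing_markers, collapse = ", ")
    ), class = "cellauth_panel_mismatch")
  }
  if (!"sample_id" %in% names(raw)) {
    abort("profile table needs a sample_id column")
  }
  if (anyDuplicated(raw$sample_id)) {
    dup <- unique(raw$sample_id[duplicated(raw$sample_id)])
    abort(paste0("duplicate sample_id: ", paste(dup, collapse = ", ")))
  }

  kinds <- setNames(marker_kind(panel$role), panel$marker_id)
  parse_errors <- list()
  parsed <- lapply(panel$marker_id, function(mk) {
    tokens <- raw[[mk]]
    out <- vapply(tokens, function(t) {
      tryCatch(parse_genotype_token(t, kinds[[mk]]),
               cellauth_parse_error = function(e) "\r__BAD__")
    }, character(1), USE.NAMES = FALSE)
    bad <- which(!is.na(out) & out == "\r__BAD__")
    if (length(bad) > 0) {
      if (strict) {
        abort(paste0(
          "unparseable genotype token '", tokens[bad[1]], "' at row ",
          bad[1], " (sample ", raw$sample_id[bad[1]], "), column ", mk
        ), class = "cellauth_parse_error")
      }
      parse_errors[[mk]] <<- tibble(
        sample_id = raw$sample_id[bad], marker_id = mk, token = tokens[bad]
      )
      out[bad] <- NA_character_
    }
    out
  })

  profiles <- tibble(
    sample_id = rep(raw$sample_id, times = nrow(panel)),
    marker_id = rep(panel$marker_id, each = nrow(raw)),
    genotype = unlist(parsed, use.names = FALSE)
  ) %>%
    arrange(match(sample_id, raw$sample_id), match(marker_id, panel$marker_id))

  if (length(parse_errors) > 0) {
    attr(profiles, "parse_errors") <- bind_rows(parse_errors)
  }

  ann <- raw[, setdiff(names(raw), panel$marker_id), drop = FALSE]
  ann <- tibble::as_tibble(ann)
  if (!"cell_line_name" %in% names(ann)) ann$cell_line_name <- ann$sample_id
  if (!"clid" %in% names(ann)) ann$clid <- NA_character_
  ann$annotated_sex <- if ("sex" %in% names(ann)) {
    s <- tolower(trimws(ann$sex))
    ifelse(s %in% c("male", "female"), s, "unknown")
  } else {
    "unknown"
  }
  ann$sex <- NULL
  ann$replicate_type <- if ("replicate_type" %in% names(ann)) {
    rt <- toupper(trimws(ann$replicate_type))
    dplyr::case_when(rt == "TR" ~ "technical", rt == "BR" ~ "biological", .default = "none")
  } else {
    "none"
  }
  if (!"replicate_group" %in% names(ann)) ann$replicate_group <- NA_character_
  if (!"synonym_group" %in% names(ann)) ann$synonym_group <- NA_character_
  ann$replicate_group[!is.na(ann$replicate_group) & !nzchar(ann$replicate_group)] <- NA_character_
  ann$synonym_group[!is.na(ann$synonym_group) & !nzchar(ann$synonym_group)] <- NA_character_
  std <- c("sample_id", "cell_line_name", "clid", "annotated_sex",
           "replicate_type", "replicate_group", "synonym_group")
  ann <- ann[, c(std, setdiff(names(ann), std)), drop = FALSE]

  list(profiles = profiles, annotations = ann)
}

#' Write a sample-by-marker profile table
#'
#' Inverse of [read_profile_table()]: emits the wide one-row-per-sample
#' layout with canonical genotype tokens (`"AB"`, `"9,9.3"`, `"No Call"`).
#' Reading the written file back reproduces the profiles and annotations
#' exactly.
#'
#' @param profiles Long profile tibble (`sample_id`, `marker_id`,
#'   `genotype`). Missing sample x marker combinations are written as
#'   no-calls.
#' @param annotations Sample-annotation tibble with one row per sample;
#'   defines the row order.
#' @param panel Marker-panel tibble; defines marker column order and token
#'   style.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`; inferred from the extension.
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, annotations, panel, path,
                                format = NULL, overwrite = FALSE) {
  validate_panel(panel)
  format <- infer_format(path, format)
  if (format == "xlsx") {
    abort("writing xlsx is not supported; use csv or tsv")
  }
  if (file.exists(path) && !overwrite) {
    abort(paste0(path, " exists; set overwrite = TRUE to replace it"))
  }
  extra <- setdiff(unique(profiles$sample_id), annotations$sample_id)
  if (length(extra) > 0) {
    abort(paste0("profiles contain samples missing from annotations: ",
                 paste(head(extra, 5), collapse = ", ")))
  }

  ann <- annotations
  out <- tibble(sample_id = ann$sample_id)
  out$cell_line_name <- ann$cell_line_name
  out$clid <- ann$clid
  out$sex <- ann$annotated_sex
  out$replicate_type <- dplyr::case_when(
    ann$replicate_type == "technical" ~ "TR",
    ann$replicate_type == "biological" ~ "BR",
    .default = "—"
  )
  out$replicate_group <- ann$replicate_group
  out$synonym_group <- ann$synonym_group
  for (nm in setdiff(names(ann), c(names(out), "annotated_sex"))) {
    out[[nm]] <- ann[[nm]]
  }

  kinds <- setNames(marker_kind(panel$role), panel$marker_id)
  wide <- profiles %>%
    filter(marker_id %in% panel$marker_id) %>%
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "marker_id",
                       values_from = "genotype")
  wide <- wide[match(out$sample_id, wide$sample_id), , drop = FALSE]
  for (mk in panel$marker_id) {
    g <- if (mk %in% names(wide)) wide[[mk]] else NA_character_
    out[[mk]] <- vapply(g, format_genotype_token, character(1),
                        kind = kinds[[mk]], USE.NAMES = FALSE)
  }

  if (format == "csv") readr::write_csv(out, path) else readr::write_tsv(out, path)
  invisible(path)
}

#' Summarise call rates of a profile set
#'
#' Computes per-sample autosomal no-call counts and the overall autosomal
#' call rate, `1 - no_calls / (n_samples x n_autosomal_markers)`. Sample x
#' marker combinations absent from `profiles` count as no-calls, so calls
#' plus no-calls always equals `n_samples x n_autosomal_markers`.
#'
#' @param profiles Long profile tibble.
#' @param panel Marker-panel tibble.
#' @return An object of class `cellauth_validation`: a list with
#'   `per_sample` (tibble: `sample_id`, `n_markers`, `n_no_call`,
#'   `call_rate`), and scalar fields `n_samples`, `n_autosomal_markers`,
#'   `n_calls`, `n_no_calls`, `call_rate`. `glance()` returns the scalars
#'   as a one-row tibble.
#' @examples
#' pop <- generate_population(synth_config(
#'   n_individuals = 5, n_replicates = 1, n_synonymous = 1, seed = 1))
#' validate_profiles(pop$profiles, pop$panel)
#' @export
validate_profiles <- function(profiles, panel) {
  validate_panel(panel)
  auto <- panel$marker_id[panel$role %in% autosomal_roles]
  samples <- unique(profiles$sample_id)
  m <- length(auto)
  called <- profiles %>%
    filter(marker_id %in% auto, !is.na(genotype)) %>%
    count(sample_id, name = "n_called")
  per_sample <- tibble(sample_id = samples) %>%
    left_join(called, by = "sample_id") %>%
    mutate(
      n_called = dplyr::coalesce(n_called, 0L),
      n_markers = m,
      n_no_call = m - n_called,
      call_rate = ifelse(m > 0, n_called / m, NA_real_)
    ) %>%
    select(sample_id, n_markers, n_no_call, call_rate)
  n_total <- length(samples) * m
  n_no_calls <- sum(per_sample$n_no_call)
  structure(
    list(
      per_sample = per_sample,
      n_samples = length(samples),
      n_autosomal_markers = m,
      n_calls = n_total - n_no_calls,
      n_no_calls = n_no_calls,
      call_rate = if (n_total > 0) 1 - n_no_calls / n_total else NA_real_
    ),
    class = "cellauth_validation"
  )
}

#' @export
print.cellauth_validation <- function(x, ...) {
  cat("Profile validation report\n")
  cat(sprintf("  samples: %d, autosomal markers: %d\n",
              x$n_samples, x$n_autosomal_markers))
  cat(sprintf("  autosomal no-calls: %d of %d (call rate %.2f%%)\n",
              x$n_no_calls, x$n_calls + x$n_no_calls, 100 * x$call_rate))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cellauth_validation <- function(x, ...) {
  tibble(
    n_samples = x$n_samples,
    n_autosomal_markers = x$n_autosomal_markers,
    n_calls = x$n_calls,
    n_no_calls = x$n_no_calls,
    call_rate = x$call_rate
  )
}

#' @exportS3Method generics::tidy
tidy.cellauth_validation <- function(x, ...) {
  x$per_sample
}
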