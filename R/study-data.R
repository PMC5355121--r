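#' Study tables: format, reader, writer and the packaged fixture
#'
#' A *study set* is a tibble with one row per cohort study and a fixed set
#' of columns. Genotype counts refer to the NUDT15 rs116855232 C>T variant:
#' `tt`/`ct`/`cc` are homozygous-variant, heterozygous and
#' homozygous-reference individuals, in cases (patients with
#' thiopurine-induced myelotoxicity) and controls (treated patients
#' without it). Per-genotype dose summaries describe the daily
#' azathioprine-equivalent maintenance dose (mg/m2) together with its
#' normalized value (dimensionless, CC reference = 1).
#'
#' Columns:
#' \describe{
#'   \item{study_id, author, year, ethnicity, disease}{study metadata;
#'     `disease` is `"IBD"` or `"ALL"`.}
#'   \item{endpoints}{comma-separated subset of
#'     `"myelotoxicity"`, `"dose"`.}
#'   \item{tt_case, ct_case, cc_case, tt_ctrl, ct_ctrl, cc_ctrl}{genotype
#'     counts; `NA` means not published (never zero).}
#'   \item{dose_<g>_n, dose_<g>_mean, dose_<g>_sd, dose_<g>_norm_mean,
#'     dose_<g>_norm_sd}{dose summary for genotype group `<g>` in
#'     `tt`, `ct`, `cc`, `tcar` (`tcar` = T carriers published
#'     pre-combined).}
#' }
#'
#' @name study_set
NULL

.count_cols <- c("tt_case", "ct_case", "cc_case", "tt_ctrl", "ct_ctrl", "cc_ctrl")
.dose_groups <- c("tt", "ct", "cc", "tcar")
.dose_fields <- c("n", "mean", "sd", "norm_mean", "norm_sd")
.dose_cols <- as.vector(outer(.dose_groups, .dose_fields,
                              function(g, f) paste0("dose_", g, "_", f)))
.required_cols <- c("study_id", "disease", .count_cols)
.all_cols <- c("study_id", "author", "year", "ethnicity", "disease",
               "endpoints", .count_cols, .dose_cols)

#' Read a study table from a tab-separated file
#'
#' Reads the TSV dialect documented in [study_set]: UTF-8,
#' tab-separated, header row, empty cell = value not published.
#' Missing optional columns (dose summaries, metadata) are added as `NA`
#' so every study set has the full column complement; when `endpoints`
#' is absent it is derived (myelotoxicity when both arms are counted,
#' dose when a CC dose summary is present).
#'
#' @param path Path to a tab-separated study table.
#' @param provenance Free-text source note attached as the
#'   `"provenance"` attribute.
#' @return A validated study-set tibble (see [study_set]).
#' @examples
#' studies <- table1_fixture()
#' tmp <- tempfile(fileext = ".tsv")
#' write_studies(studies, tmp)
#' identical_set <- read_studies(tmp)
#' @export
read_studies <- function(path, provenance = path) {
  if (!file.exists(path)) {
    abort(paste0("study file not found: ", path))
  }
  header <- names(readr::read_tsv(path, n_max = 0,
                                  col_types = readr::cols(),
                                  progress = FALSE))
  spec <- readr::cols(.default = readr::col_double())
  for (col in intersect(c("study_id", "disease", "author", "ethnicity",
                          "endpoints"), header)) {
    spec$cols[[col]] <- readr::col_character()
  }
  tab <- readr::read_tsv(path, col_types = spec, na = c("", "NA"),
                         progress = FALSE)
  missing_cols <- setdiff(.required_cols, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("study file is missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  parse_problems <- readr::problems(tab)
  if (nrow(parse_problems) > 0) {
    first <- parse_problems[1, ]
    abort(sprintf("malformed study file: line %d, column %d (%s)",
                  first$row + 1L, first$col, first$expected))
  }
  for (col in setdiff(.all_cols, names(tab))) {
    tab[[col]] <- if (col %in% c("author", "ethnicity", "endpoints")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  tab <- tab[, .all_cols]
  if (any(is.na(tab$endpoints))) {
    tab$endpoints <- ifelse(is.na(tab$endpoints),
                            derive_endpoints(tab), tab$endpoints)
  }
  new_study_set(tab, provenance)
}

derive_endpoints <- function(tab) {
  has_arms <- stats::complete.cases(tab[, .count_cols])
  has_dose <- !is.na(tab$dose_cc_norm_mean)
  ep <- ifelse(has_arms & has_dose, "myelotoxicity,dose",
        ifelse(has_arms, "myelotoxicity",
        ifelse(has_dose, "dose", NA_character_)))
  ep
}

new_study_set <- function(tab, provenance = NULL) {
  tab <- as_tibble(tab)
  validate_studies(tab)
  class(tab) <- c("study_set", class(tab))
  attr(tab, "provenance") <- provenance %||% "unspecified"
  tab
}

#' Validate a study set
#'
#' Checks the structural invariants of a study-set tibble: required
#' columns present, unique study ids, non-negative integer genotype
#' counts, myelotoxicity studies counted in both arms, and a positive CC
#' reference dose for every dose study. Called by the readers and
#' generators; exported so externally assembled tibbles can be checked.
#'
#' @param studies A study-set tibble.
#' @return `studies`, invisibly, if valid; otherwise an error.
#' @export
validate_studies <- function(studies) {
  missing_cols <- setdiff(.required_cols, names(studies))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(studies$study_id)) {
    dup <- unique(studies$study_id[duplicated(studies$study_id)])
    abort(paste0("duplicate study_id: ", paste(dup, collapse = ", ")))
  }
  counts <- as.matrix(studies[, .count_cols])
  bad <- which(counts < 0 | (is.finite(counts) & counts != round(counts)),
               arr.ind = TRUE)
  if (length(bad) > 0) {
    abort(sprintf(
      "genotype counts must be non-negative integers (study %s, column %s)",
      studies$study_id[bad[1, 1]], .count_cols[bad[1, 2]]))
  }
  if ("endpoints" %in% names(studies)) {
    myelo <- has_endpoint(studies, "myelotoxicity")
    both_arms <- stats::complete.cases(studies[, .count_cols])
    if (any(myelo & !both_arms)) {
      abort(paste0("myelotoxicity studies need counts in both arms: ",
                   paste(studies$study_id[myelo & !both_arms],
                         collapse = ", ")))
    }
    dose <- has_endpoint(studies, "dose")
    if ("dose_cc_norm_mean" %in% names(studies)) {
      # a raw CC mean qualifies too: normalization may not have run yet
      cc_ok <- (!is.na(studies$dose_cc_norm_mean) &
                  studies$dose_cc_norm_mean > 0) |
        (!is.na(studies$dose_cc_mean) & studies$dose_cc_mean > 0)
      if (any(dose & !cc_ok)) {
        abort(paste0("dose studies need a CC reference dose summary: ",
                     paste(studies$study_id[dose & !cc_ok],
                           collapse = ", ")))
      }
    }
  }
  invisible(studies)
}

has_endpoint <- function(studies, endpoint) {
  vapply(strsplit(studies$endpoints %||% character(0), ","),
         function(x) endpoint %in% trimws(x), logical(1))
}

#' Subset a study set by endpoint
#'
#' @param studies A study-set tibble.
#' @param endpoint `"myelotoxicity"` or `"dose"`.
#' @return The rows contributing to that endpoint.
#' @export
filter_endpoint <- function(studies, endpoint = c("myelotoxicity", "dose")) {
  endpoint <- match.arg(endpoint)
  studies[has_endpoint(studies, endpoint), ]
}

#' The published rs116855232 study table
#'
#' Transcription of the characteristics table of the meta-analysis:
#' 15 cohort rows from 11 articles, jointly contributing 20
#' endpoint-cohorts -- 7 case-control studies for myelotoxicity
#' susceptibility (602 cases, 1150 controls) and 13 cohorts for
#' thiopurine intolerance dose (2745 patients). Articles contributing
#' several ancestry cohorts appear as separate rows. Dose rows published
#' pre-combined over T carriers are stored under the `tcar` group;
#' single-patient TT groups carry a mean but no SD, exactly as
#' published.
#'
#' @return A study-set tibble of 15 rows (see [study_set]).
#' @examples
#' studies <- table1_fixture()
#' sum(filter_endpoint(studies, "myelotoxicity")$tt_case)
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "nudt15_rs116855232_studies.tsv",
                      package = "thiometa", mustWork = TRUE)
  read_studies(path, provenance = "packaged transcription of the published study characteristics table")
}

#' Write a study set to a tab-separated file
#'
#' Emits the same TSV dialect [read_studies()] accepts; `NA` cells are
#' written empty so absence round-trips.
#'
#' @param studies A study-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  validate_studies(studies)
  out <- as_tibble(studies)[, intersect(.all_cols, names(studies))]
  class(out) <- class(tibble())
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.study_set <- function(x, ...) {
  myelo <- sum(has_endpoint(x, "myelotoxicity"))
  dose <- sum(has_endpoint(x, "dose"))
  cat(sprintf("# study_set: %d cohort rows (%d myelotoxicity, %d dose)\n",
              nrow(x), myelo, dose))
  cat(sprintf("# provenance: %s\n", attr(x, "provenance")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
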