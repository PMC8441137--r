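#' Study-type and recovery-category levels
#'
#' The audit schema crosses species (human vs non-human) with design
#' (experimental vs observational) into four study types, and codes the
#' outcome of the data search into five categories, of which `online` and
#' `received` count as recovered.
#'
#' @return A character vector of levels.
#' @export
study_types <- function() {
  c("human_experimental", "human_observational",
    "nonhuman_experimental", "nonhuman_observational")
}

#' @rdname study_types
#' @export
recovery_categories <- function() {
  c("online", "received", "lost", "no_response", "no_request")
}

# categories counting as a successful stage-1 recovery
recovered_categories <- function() c("online", "received")

#' Assemble and validate an audit dataset
#'
#' Bundles the per-paper audit table and the per-paper results table of the
#' reproduction subsample into a validated dataset. Derived columns
#' (`age`, `recovered`) are recomputed from `pub_year`, `reference_year` and
#' `recovery_category`, and all structural invariants are enforced:
#' unique paper ids, known study types and recovery categories, non-negative
#' ages, monotone nesting of the stage counts
#' (`n_results >= n_data_usable >= n_analysis_clear >= n_results_agree`),
#' and referential integrity of the results rows (every result paper must be
#' a recovered paper).
#'
#' @param papers Data frame with columns `paper_id`, `pub_year`,
#'   `study_type`, `recovery_category`.
#' @param results Optional data frame with columns `paper_id`, `n_results`,
#'   `n_data_usable`, `n_analysis_clear`, `n_results_agree`. May be `NULL`
#'   when only the recovery stage is audited.
#' @param reference_year Integer year from which publication age is counted.
#'   Defaults to 2019, one year after the most recent publications the
#'   audit design targets.
#' @return An object of class `audit_data`: a list with tibbles `papers`
#'   and `results` plus the `reference_year`.
#' @export
audit_data <- function(papers, results = NULL, reference_year = 2019) {
  papers <- check_columns(papers, c("paper_id", "pub_year", "study_type",
                                    "recovery_category"), "papers")
  papers <- dplyr::mutate(
    papers,
    paper_id = as.character(.data$paper_id),
    pub_year = as.integer(.data$pub_year),
    study_type = as.character(.data$study_type),
    recovery_category = as.character(.data$recovery_category)
  )
  if (anyDuplicated(papers$paper_id)) {
    dup <- papers$paper_id[duplicated(papers$paper_id)][1]
    stop("duplicate paper_id in papers table: '", dup, "'", call. = FALSE)
  }
  bad_type <- setdiff(unique(papers$study_type), study_types())
  if (length(bad_type)) {
    stop("unknown study_type label(s): ", paste(bad_type, collapse = ", "),
         "; expected one of ", paste(study_types(), collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(papers$recovery_category), recovery_categories())
  if (length(bad_cat)) {
    stop("unknown recovery_category label(s): ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  papers <- dplyr::mutate(
    papers,
    age = as.integer(reference_year) - .data$pub_year,
    recovered = as.integer(.data$recovery_category %in% recovered_categories())
  )
  if (any(papers$age < 0)) {
    bad <- papers$paper_id[papers$age < 0][1]
    stop("paper '", bad, "' has pub_year after reference_year (negative age)",
         call. = FALSE)
  }

  if (is.null(results)) {
    results <- tibble::tibble(paper_id = character(), n_results = integer(),
                              n_data_usable = integer(),
                              n_analysis_clear = integer(),
                              n_results_agree = integer())
  } else {
    results <- check_columns(results, c("paper_id", "n_results",
                                        "n_data_usable", "n_analysis_clear",
                                        "n_results_agree"), "results")
    results <- dplyr::mutate(
      results,
      paper_id = as.character(.data$paper_id),
      dplyr::across(dplyr::all_of(c("n_results", "n_data_usable",
                                    "n_analysis_clear", "n_results_agree")),
                    as.integer)
    )
    if (any(results$n_results < 1)) {
      stop("results rows must have n_results >= 1", call. = FALSE)
    }
    mono <- with(results, n_results_agree <= n_analysis_clear &
                   n_analysis_clear <= n_data_usable &
                   n_data_usable <= n_results & n_results_agree >= 0)
    if (any(!mono)) {
      bad <- results$paper_id[!mono][1]
      stop("stage counts for paper '", bad, "' violate monotone nesting ",
           "(need 0 <= n_results_agree <= n_analysis_clear <= ",
           "n_data_usable <= n_results)", call. = FALSE)
    }
    missing_id <- setdiff(results$paper_id, papers$paper_id)
    if (length(missing_id)) {
      stop("results paper_id not present in papers table: '",
           missing_id[1], "'", call. = FALSE)
    }
    rec <- papers$recovered[match(results$paper_id, papers$paper_id)]
    if (any(rec == 0L)) {
      bad <- results$paper_id[rec == 0L][1]
      stop("results row for paper '", bad,
           "' but its data were not recovered (stage 1 failed)",
           call. = FALSE)
    }
    if (anyDuplicated(results$paper_id)) {
      dup <- results$paper_id[duplicated(results$paper_id)][1]
      stop("duplicate paper_id in results table: '", dup, "'", call. = FALSE)
    }
  }

  structure(
    list(papers = tibble::as_tibble(papers),
         results = tibble::as_tibble(results),
         reference_year = as.integer(reference_year)),
    class = "audit_data"
  )
}

check_columns <- function(df, needed, what) {
  if (!is.data.frame(df)) {
    stop("`", what, "` must be a data frame", call. = FALSE)
  }
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(what, " table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @export
print.audit_data <- function(x, ...) {
  cat("<audit_data> ", nrow(x$papers), " papers, ",
      nrow(x$results), " results rows (reference year ",
      x$reference_year, ")\n", sep = "")
  cat("  recovered: ", sum(x$papers$recovered), " (",
      round(100 * mean(x$papers$recovered), 1), "%)\n", sep = "")
  if (nrow(x$results)) {
    cat("  results identified: ", sum(x$results$n_results), "\n", sep = "")
  }
  invisible(x)
}

#' Read an audit dataset from delimited tables
#'
#' Reads the comma-separated papers and results tables (UTF-8, header row)
#' and validates them with [audit_data()].
#'
#' @param papers_path Path to `papers.csv` (`paper_id`, `pub_year`,
#'   `study_type`, `recovery_category`).
#' @param results_path Optional path to `results.csv` (`paper_id`,
#'   `n_results`, `n_data_usable`, `n_analysis_clear`, `n_results_agree`).
#' @inheritParams audit_data
#' @return An `audit_data` object.
#' @export
read_audit <- function(papers_path, results_path = NULL,
                       reference_year = 2019) {
  if (!file.exists(papers_path)) {
    stop("papers file not found: ", papers_path, call. = FALSE)
  }
  papers <- readr::read_csv(papers_path, show_col_types = FALSE,
                            progress = FALSE)
  results <- NULL
  if (!is.null(results_path)) {
    if (!file.exists(results_path)) {
      stop("results file not found: ", results_path, call. = FALSE)
    }
    results <- readr::read_csv(results_path, show_col_types = FALSE,
                               progress = FALSE)
  }
  audit_data(papers, results, reference_year = reference_year)
}

#' Write an audit dataset to delimited tables
#'
#' Serialises the dataset so that [read_audit()] reproduces it
#' field-for-field; writing the same dataset twice yields byte-identical
#' files. Only the schema columns are written (derived columns are
#' recomputed on read).
#'
#' @param ds An `audit_data` object.
#' @param papers_path,results_path Output paths.
#' @return `ds`, invisibly.
#' @export
write_audit <- function(ds, papers_path, results_path = NULL) {
  stopifnot(inherits(ds, "audit_data"))
  readr::write_csv(
    dplyr::select(ds$papers, dplyr::all_of(c("paper_id", "pub_year",
                                             "study_type",
                                             "recovery_category"))),
    papers_path, progress = FALSE)
  if (!is.null(results_path)) {
    readr::write_csv(
      dplyr::select(ds$results, dplyr::all_of(c("paper_id", "n_results",
                                                "n_data_usable",
                                                "n_analysis_clear",
                                                "n_results_agree"))),
      results_path, progress = FALSE)
  }
  invisible(ds)
}

#' Count bookkeeping for an audit
#'
#' Tabulates the margins of the audit: papers per recovery category and per
#' study type, the recovered total and fraction (recovered = available
#' online + received from authors), the number of author responses
#' (received + lost, i.e. requests that got any informative reply), and the
#' totals of each reproduction stage over the results subsample.
#'
#' @param ds An `audit_data` object.
#' @return An `audit_counts` object: list with tibbles `by_category`,
#'   `by_type`, `stage_totals` and scalars `n_papers`, `recovered`,
#'   `recovered_frac`, `responses`, `response_frac`.
#' @export
summarize_counts <- function(ds) {
  stopifnot(inherits(ds, "audit_data"))
  p <- ds$papers
  by_category <- p |>
    dplyr::count(recovery_category = factor(.data$recovery_category,
                                            recovery_categories()),
                 .drop = FALSE, name = "n_papers") |>
    dplyr::mutate(recovery_category = as.character(.data$recovery_category))
  by_type <- p |>
    dplyr::count(study_type = factor(.data$study_type, study_types()),
                 .drop = FALSE, name = "n_papers") |>
    dplyr::mutate(study_type = as.character(.data$study_type))
  recovered <- sum(p$recovered)
  responses <- sum(p$recovery_category %in% c("received", "lost"))
  stage_totals <- tibble::tibble(
    stage = c("results_identified", "data_usable", "analysis_clear",
              "results_agree"),
    n = c(sum(ds$results$n_results), sum(ds$results$n_data_usable),
          sum(ds$results$n_analysis_clear), sum(ds$results$n_results_agree))
  )
  structure(
    list(n_papers = nrow(p),
         by_category = by_category,
         by_type = by_type,
         recovered = recovered,
         recovered_frac = recovered / nrow(p),
         responses = responses,
         response_frac = responses / nrow(p),
         n_result_papers = nrow(ds$results),
         stage_totals = stage_totals),
    class = "audit_counts"
  )
}

#' @export
print.audit_counts <- function(x, ...) {
  cat("Audit margins\n")
  cat(sprintf("  papers:            %d\n", x$n_papers))
  for (i in seq_len(nrow(x$by_category))) {
    cat(sprintf("  %-18s %d (%s%%)\n",
                paste0(x$by_category$recovery_category[i], ":"),
                x$by_category$n_papers[i],
                round(100 * x$by_category$n_papers[i] / x$n_papers)))
  }
  cat(sprintf("  recovered:         %d (%s%%)\n", x$recovered,
              round(100 * x$recovered_frac)))
  cat(sprintf("  author responses:  %d (%s%%)\n", x$responses,
              round(100 * x$response_frac)))
  if (x$n_result_papers > 0) {
    cat(sprintf("  reproduction subsample: %d papers\n", x$n_result_papers))
    for (i in seq_len(nrow(x$stage_totals))) {
      cat(sprintf("  %-18s %d\n", paste0(x$stage_totals$stage[i], ":"),
                  x$stage_totals$n[i]))
    }
  }
  invisible(x)
}

#' @method tidy audit_counts
#' @export
tidy.audit_counts <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$by_category, term = paste0("category_",
                                                  .data$recovery_category),
                     n = .data$n_papers),
    dplyr::transmute(x$by_type, term = paste0("type_", .data$study_type),
                     n = .data$n_papers),
    tibble::tibble(term = c("papers", "recovered", "responses"),
                   n = c(x$n_papers, x$recovered, x$responses)),
    dplyr::transmute(x$stage_totals, term = .data$stage, n = .data$n)
  ) |>
    dplyr::mutate(fraction = .data$n / x$n_papers)
}

# named age lookup (paper_id -> years since publication)
paper_ages <- function(ds) {
  stats::setNames(ds$papers$age, ds$papers$paper_id)
}
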