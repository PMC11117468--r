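#' @title Patient cohort objects
#' @description
#' A cohort is a tibble with one row per patient and a fixed column
#' vocabulary, carrying a `provenance` attribute (`"observed"` or
#' `"synthetic"`) and, for synthetic cohorts, the generator seed.
#'
#' Required columns:
#' \describe{
#'   \item{id}{opaque unique patient identifier (character)}
#'   \item{age}{years, integer 18--110}
#'   \item{sex}{`"female"` or `"male"`}
#'   \item{lc_type}{involved monoclonal light-chain isotype, `"kappa"` or
#'     `"lambda"`}
#'   \item{serum_creatinine}{mg/dL, > 0; may be `NA` when `egfr` is given}
#'   \item{egfr}{mL/min/1.73 m\eqn{^2}, > 0; completed from creatinine via
#'     CKD-EPI when absent}
#'   \item{involved_flc_serum}{involved serum free light chain, mg/dL, >= 0}
#'   \item{involved_lc_urine}{involved urine light chain, mg/dL, >= 0}
#'   \item{proteinuria}{mg per 24 h, >= 0; may be `NA` (see
#'     [apply_rule()] for the consequences)}
#'   \item{histology}{canonical biopsy label, see [normalize_histology()]}
#' }
#' An optional `histology_detail` column retains the free-text subtype for
#' rows normalised to `"other"`.
#' @name cohort
NULL

cohort_columns <- c(
  "id", "age", "sex", "lc_type", "serum_creatinine", "egfr",
  "involved_flc_serum", "involved_lc_urine", "proteinuria", "histology"
)

histology_levels <- c(
  "cast_nephropathy", "light_chain_proximal_tubulopathy", "al_amyloidosis",
  "midd", "nephroangiosclerosis", "thrombotic_microangiopathy", "other"
)

#' Normalise free-text biopsy diagnoses to canonical labels
#'
#' Biopsy reports name diagnoses as prose ("AL amyloidosis", "LCDD",
#' "Cast-Nephropathy"). Matching is case-insensitive after collapsing
#' whitespace/hyphens; unrecognised diagnoses map to `"other"` with the
#' original text retained by the caller.
#'
#' @param x Character vector of diagnosis labels.
#' @return Character vector over the closed label set
#'   `cast_nephropathy`, `light_chain_proximal_tubulopathy`,
#'   `al_amyloidosis`, `midd`, `nephroangiosclerosis`,
#'   `thrombotic_microangiopathy`, `other`.
#' @export
#' @examples
#' normalize_histology(c("Cast nephropathy", "LCDD", "IgA glomerulonephritis"))
normalize_histology <- function(x) {
  key <- gsub("[^a-z0-9]+", "_", tolower(trimws(as.character(x))))
  key <- gsub("^_|_$", "", key)
  synonyms <- c(
    cast_nephropathy = "cast_nephropathy",
    cn = "cast_nephropathy",
    myeloma_cast_nephropathy = "cast_nephropathy",
    light_chain_proximal_tubulopathy = "light_chain_proximal_tubulopathy",
    lc_proximal_tubulopathy = "light_chain_proximal_tubulopathy",
    proximal_tubulopathy = "light_chain_proximal_tubulopathy",
    lcpt = "light_chain_proximal_tubulopathy",
    al_amyloidosis = "al_amyloidosis",
    amyloidosis = "al_amyloidosis",
    ala = "al_amyloidosis",
    midd = "midd",
    lcdd = "midd",
    hcdd = "midd",
    light_chain_deposition_disease = "midd",
    monoclonal_immunoglobulin_deposition_disease = "midd",
    nephroangiosclerosis = "nephroangiosclerosis",
    thrombotic_microangiopathy = "thrombotic_microangiopathy",
    tma = "thrombotic_microangiopathy"
  )
  out <- unname(synonyms[key])
  out[is.na(out)] <- "other"
  out
}

#' Construct and validate a cohort
#'
#' Validates the patient-level invariants, completes missing eGFR from
#' creatinine via CKD-EPI, and checks creatinine/eGFR mutual consistency
#' under the CKD-EPI forward map.
#'
#' @param data A data frame with the [cohort] columns.
#' @param provenance `"observed"` or `"synthetic"`.
#' @param seed Generator seed for synthetic cohorts, or `NA`.
#' @param strict If `TRUE` (default) any invariant violation aborts; if
#'   `FALSE`, offending rows are dropped and reported via a warning and
#'   the `"dropped"` attribute (a tibble of `id`, `reason`).
#' @param egfr_tol Relative tolerance for creatinine/eGFR consistency
#'   (default 0.05). In lenient mode an inconsistent pair keeps the
#'   supplied eGFR (the analysis-bearing quantity) and is logged.
#' @param ckdepi A [ckdepi_params()] object used for completion and
#'   consistency checking.
#' @return A validated cohort tibble (class `lcq_cohort`).
#' @export
as_cohort <- function(data, provenance = "observed", seed = NA_integer_,
                      strict = TRUE, egfr_tol = 0.05,
                      ckdepi = ckdepi_params()) {
  stopifnot(is.data.frame(data))
  provenance <- match.arg(provenance, c("observed", "synthetic"))
  missing_cols <- setdiff(cohort_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    abort(paste0("duplicate patient id(s): ",
                 paste(unique(data$id[duplicated(data$id)]), collapse = ", ")))
  }
  for (col in c("age", "serum_creatinine", "egfr", "involved_flc_serum",
                "involved_lc_urine", "proteinuria")) {
    if (!is.numeric(data[[col]])) {
      abort(paste0("column `", col, "` must be numeric"))
    }
  }
  raw_hist <- as.character(data$histology)
  norm_hist <- normalize_histology(raw_hist)
  if (!"histology_detail" %in% names(data)) {
    data$histology_detail <- ifelse(norm_hist == "other", raw_hist, NA_character_)
  }
  data$histology <- norm_hist
  data$sex <- as.character(data$sex)
  data$lc_type <- as.character(data$lc_type)

  reasons <- rep(NA_character_, nrow(data))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- why
  }
  flag(!data$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  flag(!data$lc_type %in% c("kappa", "lambda"), "lc_type must be 'kappa' or 'lambda'")
  flag(is.na(data$age) | data$age < 18 | data$age > 110, "age outside [18, 110]")
  flag(!is.na(data$serum_creatinine) & data$serum_creatinine <= 0,
       "serum_creatinine must be > 0")
  flag(!is.na(data$egfr) & data$egfr <= 0, "egfr must be > 0")
  flag(is.na(data$egfr) & is.na(data$serum_creatinine),
       "one of egfr or serum_creatinine is required")
  flag(is.na(data$involved_lc_urine) | data$involved_lc_urine < 0,
       "involved_lc_urine must be >= 0")
  flag(!is.na(data$involved_flc_serum) & data$involved_flc_serum < 0,
       "involved_flc_serum must be >= 0")
  flag(!is.na(data$proteinuria) & data$proteinuria < 0,
       "proteinuria must be >= 0")

  # complete eGFR from creatinine where rows are otherwise sound
  fill <- is.na(data$egfr) & is.na(reasons)
  if (any(fill)) {
    data$egfr[fill] <- egfr_ckdepi(
      data$serum_creatinine[fill], data$age[fill], data$sex[fill], ckdepi
    )
  }
  both <- !is.na(data$egfr) & !is.na(data$serum_creatinine) & is.na(reasons)
  if (any(both)) {
    implied <- egfr_ckdepi(data$serum_creatinine[both], data$age[both],
                           data$sex[both], ckdepi)
    off <- abs(data$egfr[both] - implied) / implied > egfr_tol
    if (strict) {
      flag(replace(logical(nrow(data)), which(both)[off], TRUE),
           sprintf("egfr inconsistent with CKD-EPI(creatinine) beyond %.0f%%",
                   100 * egfr_tol))
    } else if (any(off)) {
      inform(paste0(sum(off), " row(s) with creatinine/eGFR mismatch beyond ",
                    100 * egfr_tol, "%; keeping the supplied eGFR"))
    }
  }

  bad <- !is.na(reasons)
  dropped <- tibble::tibble(id = data$id[bad], reason = reasons[bad])
  if (any(bad)) {
    if (strict) {
      abort(paste0(
        "invalid cohort row(s): ",
        paste(sprintf("[%s] %s", dropped$id, dropped$reason), collapse = "; ")
      ))
    }
    warn(paste0("dropped ", sum(bad), " invalid row(s); see attr(, 'dropped')"))
    data <- data[!bad, , drop = FALSE]
  }
  if (nrow(data) == 0) abort("cohort has no valid rows")

  data <- data[, c(cohort_columns, "histology_detail")]
  structure(data,
            class = c("lcq_cohort", class(tibble::tibble())),
            provenance = provenance,
            seed = seed,
            dropped = dropped)
}

#' @export
print.lcq_cohort <- function(x, ...) {
  cat(sprintf("<lcq_cohort> %d patients (%s%s)\n", nrow(x),
              attr(x, "provenance"),
              if (!is.na(attr(x, "seed"))) paste0(", seed ", attr(x, "seed")) else ""))
  NextMethod()
}

#' Read a cohort from a delimited text file
#'
#' Accepts comma- or tab-separated values with a header naming the
#' [cohort] columns; decimal point mandatory. Leading `#` comment lines
#' are metadata (provenance / seed written by [write_cohort()]).
#'
#' @param path Path to the file.
#' @param strict Passed to [as_cohort()]: abort on invalid rows (`TRUE`)
#'   or drop and log them (`FALSE`).
#' @param delim Field delimiter; `NULL` (default) infers `"\t"` for
#'   `.tsv`/`.tab` files and `","` otherwise.
#' @inheritParams as_cohort
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, strict = TRUE, delim = NULL,
                        egfr_tol = 0.05, ckdepi = ckdepi_params()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  meta <- list(provenance = "observed", seed = NA_integer_)
  first <- readLines(path, n = 5L)
  for (line in grep("^#", first, value = TRUE)) {
    m <- regmatches(line, regexec("provenance:\\s*(\\w+)", line))[[1]]
    if (length(m) == 2) meta$provenance <- m[2]
    m <- regmatches(line, regexec("seed:\\s*(-?\\d+)", line))[[1]]
    if (length(m) == 2) meta$seed <- as.integer(m[2])
  }
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  as_cohort(raw, provenance = meta$provenance, seed = meta$seed,
            strict = strict, egfr_tol = egfr_tol, ckdepi = ckdepi)
}

#' Write a cohort to a delimited text file
#'
#' Writes a header comment line carrying provenance (and generator seed
#' for synthetic cohorts) followed by comma-separated values at full
#' numeric precision, so that [read_cohort()] round-trips the cohort
#' field-identically.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "lcq_cohort"))
  if (nrow(cohort) == 0) abort("refusing to write an empty cohort")
  seed <- attr(cohort, "seed")
  header <- paste0("# lcquotient cohort; provenance: ", attr(cohort, "provenance"),
                   if (!is.na(seed)) paste0("; seed: ", seed) else "")
  body <- readr::format_csv(as.data.frame(cohort), na = "")
  writeLines(c(header, sub("\n+$", "", body)), path)
  invisible(path)
}

#' Cohort composition counts
#'
#' Patient counts by biopsy histology, by involved light-chain type and
#' by sex, plus the cast-nephropathy ground-truth split.
#'
#' @param cohort A cohort tibble.
#' @return A list with tibbles `histology`, `lc_type`, `sex`, and scalars
#'   `n` and `n_cn` (biopsy-proven cast nephropathy).
#' @export
#' @examples
#' ch <- generate_cohort(seed = 1)
#' cohort_summary_counts(ch)$n_cn
cohort_summary_counts <- function(cohort) {
  stopifnot(inherits(cohort, "lcq_cohort"), nrow(cohort) > 0)
  count_of <- function(var) {
    tab <- table(as.character(cohort[[var]]))
    tab <- tab[order(-tab, names(tab))]
    out <- tibble::tibble(level = names(tab), n = as.integer(tab))
    names(out)[1] <- var
    out
  }
  list(
    n = nrow(cohort),
    n_cn = sum(cohort$histology == "cast_nephropathy"),
    histology = count_of("histology"),
    lc_type = count_of("lc_type"),
    sex = count_of("sex")
  )
}

#' Map histology labels to the four comparison groups
#'
#' Group comparisons and the synthetic generator work on four groups:
#' cast nephropathy (`CN`), AL amyloidosis (`ALA`), monoclonal
#' immunoglobulin deposition disease (`MIDD`) and everything else
#' (`Others`).
#'
#' @param histology Character vector of canonical histology labels.
#' @return Factor with levels `CN`, `ALA`, `MIDD`, `Others`.
#' @export
histology_group <- function(histology) {
  out <- dplyr::case_match(
    histology,
    "cast_nephropathy" ~ "CN",
    "al_amyloidosis" ~ "ALA",
    "midd" ~ "MIDD",
    .default = "Others"
  )
  factor(out, levels = c("CN", "ALA", "MIDD", "Others"))
}
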