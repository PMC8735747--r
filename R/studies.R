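#' @keywords internal
"_PACKAGE"

# Required columns of a study table; genotype counts are CC (wild-type
# homozygote), CT (heterozygote), TT (mutant homozygote) per arm.
.count_cols <- c("case_cc", "case_ct", "case_tt",
                 "control_cc", "control_ct", "control_tt")
.required_cols <- c("study_id", "author", "year", "subgroup", .count_cols)
.optional_cols <- c("design", "quality_score", "case_n", "control_n")

#' Construct a validated study table
#'
#' A study table holds one row per case-control study: identifying metadata
#' (study id, author, year, a free-form subgroup label such as ethnicity,
#' optional design and quality score) and the genotype counts CC/CT/TT for
#' the case and control arms. The mutant allele is written T and the
#' wild-type allele C throughout the package.
#'
#' @param df data.frame with at least the columns `study_id`, `author`,
#'   `year`, `subgroup`, `case_cc`, `case_ct`, `case_tt`, `control_cc`,
#'   `control_ct`, `control_tt`; optionally `design`, `quality_score`,
#'   `case_n`, `control_n`. Row order is preserved and determines reporting
#'   order.
#' @param provenance character scalar recording where the data came from.
#' @return An object of class `study_table` (a data.frame).
#' @details Validation enforces: unique study ids; non-negative integer
#'   genotype counts; each arm total of at least one individual; and, when a
#'   declared `case_n`/`control_n` is present, agreement with the genotype
#'   sum. Violations raise errors naming the offending study and field.
#' @export
#' @examples
#' tab <- study_table(data.frame(
#'   study_id = "s1", author = "Smith", year = 2020, subgroup = "Asian",
#'   case_cc = 90, case_ct = 9, case_tt = 1,
#'   control_cc = 88, control_ct = 11, control_tt = 1))
#' tab
study_table <- function(df, provenance = "in-memory") {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols) > 0L)
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$study_id))
    stop("duplicate study_id: ",
         paste(unique(df$study_id[duplicated(df$study_id)]), collapse = ", "),
         call. = FALSE)
  for (col in .count_cols) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop("column '", col, "' must be numeric with no missing values",
           call. = FALSE)
    bad <- which(v < 0 | v != round(v))
    if (length(bad) > 0L)
      stop("study '", df$study_id[bad[1L]], "': field '", col,
           "' must be a non-negative integer (got ", v[bad[1L]], ")",
           call. = FALSE)
    df[[col]] <- as.integer(round(v))
  }
  case_n <- df$case_cc + df$case_ct + df$case_tt
  control_n <- df$control_cc + df$control_ct + df$control_tt
  for (arm in c("case", "control")) {
    n <- if (arm == "case") case_n else control_n
    bad <- which(n < 1L)
    if (length(bad) > 0L)
      stop("study '", df$study_id[bad[1L]], "': ", arm,
           " genotype counts sum to zero; each arm needs at least one individual",
           call. = FALSE)
    decl <- df[[paste0(arm, "_n")]]
    if (!is.null(decl)) {
      bad <- which(!is.na(decl) & decl != n)
      if (length(bad) > 0L)
        stop("study '", df$study_id[bad[1L]], "': declared ", arm,
             "_n (", decl[bad[1L]], ") does not match genotype sum (",
             n[bad[1L]], ")", call. = FALSE)
    }
  }
  keep <- c(.required_cols, intersect(.optional_cols, names(df)))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("study_table", "data.frame"),
            provenance = provenance)
}

#' Read a study table from delimited text
#'
#' Reads a comma- or tab-delimited file with one row per study and a header
#' naming the study-table columns (see [study_table()]), validates every row,
#' and preserves row order.
#'
#' @param path path to a CSV or TSV file.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A validated [study_table()].
#' @seealso [write_studies()] for the inverse operation.
#' @export
read_studies <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  study_table(df, provenance = path)
}

#' Write a study table to delimited text
#'
#' @param x a [study_table()].
#' @param path output file path.
#' @param sep field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_studies <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "study_table"))
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Bundled dataset: VEGFR2 rs2305948 and glioma risk
#'
#' The four published case-control studies of the VEGFR2 polymorphism
#' rs2305948 and glioma susceptibility (1595 cases, 1657 controls):
#' Vasconcelos 2019 (Non-Asian, population-based), Gao 2016 (Asian,
#' population-based), Chen 2012 (Asian, population-based) and Zhang 2016
#' (Asian, hospital-based), with genotype counts per arm, study design and
#' Newcastle-Ottawa quality score. The same table ships as a CSV under
#' `inst/extdata/rs2305948_glioma.csv`.
#'
#' @return A [study_table()] with four rows, in publication order.
#' @export
#' @examples
#' glioma_rs2305948()
glioma_rs2305948 <- function() {
  study_table(data.frame(
    study_id = c("Vasconcelos2019", "Gao2016", "Chen2012", "Zhang2016"),
    author = c("Vasconcelos", "Gao", "Chen", "Zhang"),
    year = c(2019L, 2016L, 2012L, 2016L),
    subgroup = c("Non-Asian", "Asian", "Asian", "Asian"),
    design = c("PB", "PB", "PB", "HB"),
    quality_score = c(7L, 8L, 7L, 8L),
    case_cc = c(155L, 91L, 558L, 332L),
    case_ct = c(47L, 46L, 171L, 117L),
    case_tt = c(3L, 20L, 27L, 28L),
    control_cc = c(144L, 101L, 629L, 364L),
    control_ct = c(53L, 48L, 173L, 101L),
    control_tt = c(8L, 11L, 13L, 12L),
    case_n = c(205L, 157L, 756L, 477L),
    control_n = c(205L, 160L, 815L, 477L),
    stringsAsFactors = FALSE
  ), provenance = "fixture")
}

#' @export
print.study_table <- function(x, ...) {
  cat("Study table (", nrow(x), " studies, ",
      sum(x$case_cc + x$case_ct + x$case_tt), " cases / ",
      sum(x$control_cc + x$control_ct + x$control_tt), " controls)\n",
      sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

# case/control genotype count vectors for study row i
.arm_counts <- function(x, i, arm = c("case", "control")) {
  arm <- match.arg(arm)
  as.integer(c(x[[paste0(arm, "_cc")]][i], x[[paste0(arm, "_ct")]][i],
               x[[paste0(arm, "_tt")]][i]))
}

# subset rows of a study table, keeping class and provenance
.subset_studies <- function(x, idx) {
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("study_table", "data.frame"),
            provenance = attr(x, "provenance"))
}
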