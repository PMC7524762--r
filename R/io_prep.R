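#' Survey and harvest tables, abundance indices, growth observations
#'
#' A herd's annual abundance index is the highest single-survey count of
#' females, juveniles and subadult males in that year (adult males are never
#' counted), plus any hunter harvest recorded for the year. Growth
#' observations are the pairs \eqn{(N_t, r_t)} with
#' \eqn{r_t = \ln(N_{t+1}/N_t)} that feed the linearized Ricker fit.
#'
#' @name io_prep
NULL

.survey_cols <- c("herd", "year", "replicate", "n_female", "n_juvenile",
                  "n_subadult_male", "n_adult_male")
.count_cols <- c("n_female", "n_juvenile", "n_subadult_male", "n_adult_male")

.read_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim))
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a survey table
#'
#' Columns (case-insensitive): herd, year, replicate, n_female, n_juvenile,
#' n_subadult_male, n_adult_male. Delimiter is inferred from the extension
#' (`.tsv` means tab, otherwise comma) and can be overridden.
#'
#' @param path CSV/TSV file path.
#' @param delim optional single-character delimiter override.
#' @return A `data.frame` of survey records, one row per (herd, year,
#'   replicate).
#' @export
read_surveys <- function(path, delim = NULL) {
  df <- .read_table(path, delim)
  names(df) <- tolower(names(df))
  missing <- setdiff(.survey_cols, names(df))
  if (length(missing))
    stop("survey table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[.survey_cols]
  validate_surveys(df)
  df
}

#' Validate survey records
#'
#' Checks the survey-record invariants: all counts non-negative integers,
#' (herd, year, replicate) unique. Errors name the offending row index.
#'
#' @param surveys data.frame of survey records.
#' @return `surveys`, invisibly.
#' @export
validate_surveys <- function(surveys) {
  for (col in .count_cols) {
    bad <- which(!is.finite(surveys[[col]]) | surveys[[col]] < 0 |
                   surveys[[col]] != round(surveys[[col]]))
    if (length(bad))
      stop("invalid count in column '", col, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(surveys$herd, surveys$year, surveys$replicate)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (herd, year, replicate) at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "))
  invisible(surveys)
}

#' Read a harvest table
#'
#' Columns (case-insensitive): herd, year, harvest.
#'
#' @inheritParams read_surveys
#' @return A `data.frame` with one row per (herd, year).
#' @export
read_harvests <- function(path, delim = NULL) {
  df <- .read_table(path, delim)
  names(df) <- tolower(names(df))
  missing <- setdiff(c("herd", "year", "harvest"), names(df))
  if (length(missing))
    stop("harvest table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$harvest) | df$harvest < 0)
  if (length(bad))
    stop("negative or non-finite harvest at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df[c("herd", "year", "harvest")]
}

#' One herd's harvest-adjusted annual abundance index
#'
#' @param herd herd identifier.
#' @param years strictly increasing integer years.
#' @param N positive abundance index per year.
#' @return A `herd_series` object. Gap pairs (non-consecutive years) are
#'   derived from `years`, never stored independently.
#' @export
herd_series <- function(herd, years, N) {
  stopifnot(length(years) == length(N), length(years) >= 1L)
  if (is.unsorted(years, strictly = TRUE)) stop("years must strictly increase")
  if (any(N <= 0)) stop("abundance index must be positive for every year")
  structure(list(herd = herd, years = as.integer(years), N = as.numeric(N)),
            class = "herd_series")
}

#' @export
print.herd_series <- function(x, ...) {
  cat("<herd_series> ", x$herd, ": ", length(x$years), " years (",
      min(x$years), "-", max(x$years), "), N in [",
      round(min(x$N), 1), ", ", round(max(x$N), 1), "]\n", sep = "")
  invisible(x)
}

#' Gap pairs of a herd series
#'
#' @param series a [herd_series].
#' @return Two-column matrix of non-consecutive adjacent year pairs.
#' @export
series_gaps <- function(series) {
  y <- series$years
  i <- which(diff(y) > 1L)
  cbind(from = y[i], to = y[i + 1L])
}

#' Build annual abundance indices from surveys and harvests
#'
#' Per herd and year the index is the maximum over survey replicates of
#' (females + juveniles + subadult males), plus that year's recorded harvest
#' (missing harvest record means zero). Adult males never enter the index.
#' Years with no surveys are absent from the series.
#'
#' @param surveys data.frame of survey records ([read_surveys] layout).
#' @param harvests optional data.frame of harvest records.
#' @return Named list of [herd_series], one per herd.
#' @export
annual_abundance_index <- function(surveys, harvests = NULL) {
  if (is.null(surveys) || nrow(surveys) == 0L) stop("empty survey set")
  validate_surveys(surveys)
  grp <- surveys$n_female + surveys$n_juvenile + surveys$n_subadult_male
  agg <- stats::aggregate(grp,
                          by = list(herd = surveys$herd, year = surveys$year),
                          FUN = max)
  names(agg)[3] <- "N"
  if (!is.null(harvests) && nrow(harvests) > 0L) {
    m <- match(paste(agg$herd, agg$year), paste(harvests$herd, harvests$year))
    add <- ifelse(is.na(m), 0, harvests$harvest[m])
    agg$N <- agg$N + add
  }
  out <- lapply(split(agg, agg$herd), function(d) {
    d <- d[order(d$year), ]
    herd_series(d$herd[1], d$year, d$N)
  })
  out[order(names(out))]
}

#' Growth observations from a herd series
#'
#' For consecutive years, \eqn{r_t = \ln(N_{t+1}/N_t)} with predictor
#' \eqn{N_t}. Pairs spanning a gap of g > 1 years are skipped under
#' `gap_policy = "skip"` (the default; it never fabricates dynamics) or
#' converted to an annualized rate \eqn{(1/g)\ln(N_{t+g}/N_t)} with
#' `span = g` under `"annualize"`.
#'
#' @param series a [herd_series] of length at least 2.
#' @param gap_policy `"skip"` or `"annualize"`.
#' @return data.frame with columns `herd`, `year_t`, `N_t`, `r_t`, `span`.
#' @export
growth_observations <- function(series, gap_policy = c("skip", "annualize")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(series, "herd_series"))
  if (length(series$years) < 2L) stop("series must have at least 2 years")
  if (any(series$N <= 0)) stop("log growth undefined for N <= 0")
  span <- diff(series$years)
  r <- log(series$N[-1] / series$N[-length(series$N)])
  obs <- data.frame(herd = series$herd,
                    year_t = series$years[-length(series$years)],
                    N_t = series$N[-length(series$N)],
                    r_t = r, span = as.integer(span))
  if (gap_policy == "skip") {
    obs <- obs[obs$span == 1L, , drop = FALSE]
  } else {
    obs$r_t <- obs$r_t / obs$span
  }
  rownames(obs) <- NULL
  obs
}

#' Growth observations for every herd in a dataset
#'
#' @param series_list named list of [herd_series].
#' @inheritParams growth_observations
#' @return Named list of growth-observation data.frames (herds with fewer
#'   than 2 usable transitions are dropped with a warning).
#' @export
dataset_growth_observations <- function(series_list,
                                        gap_policy = c("skip", "annualize")) {
  gap_policy <- match.arg(gap_policy)
  out <- lapply(series_list, growth_observations, gap_policy = gap_policy)
  short <- names(out)[vapply(out, nrow, 0L) < 2L]
  if (length(short)) {
    warning("dropping herd(s) with < 2 growth observations: ",
            paste(short, collapse = ", "))
    out <- out[setdiff(names(out), short)]
  }
  out
}
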