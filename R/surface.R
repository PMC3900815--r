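#' Construct a mortality surface
#'
#' A mortality surface is an age-group-by-calendar-year matrix of mortality
#' rates (deaths per 100,000 person-years), the raw object the whole pipeline
#' consumes. Rows index years, columns index age groups. Zero rates are
#' treated as missing because the analysis works on the log scale.
#'
#' @param rates T x A numeric matrix of rates per 100,000; rows are years.
#' @param years integer vector of T consecutive calendar years.
#' @param age_groups either a 2-column matrix/data.frame of integer (low, high)
#'   age bounds, or a character vector of labels like \code{"45-49"}, or a
#'   numeric vector of age midpoints.
#' @return an object of class \code{mortality_surface} with fields
#'   \code{rates}, \code{years}, \code{age_groups}, \code{age_midpoints},
#'   \code{missing} (logical T x A mask).
#' @export
mortality_surface <- function(rates, years, age_groups) {
  rates <- as.matrix(rates)
  years <- as.integer(years)
  if (length(years) != nrow(rates)) {
    stop("length(years) must equal nrow(rates)")
  }
  if (is.unsorted(years, strictly = TRUE) || any(diff(years) != 1L)) {
    stop("years must be strictly increasing consecutive calendar years")
  }
  ag <- normalize_age_groups(age_groups)
  if (length(ag$midpoints) != ncol(rates)) {
    stop("number of age groups must equal ncol(rates)")
  }
  if (is.unsorted(ag$midpoints, strictly = TRUE)) {
    stop("age midpoints must be strictly increasing")
  }
  miss <- !is.finite(rates)
  if (any(rates[!miss] < 0)) stop("negative mortality rates are not allowed")
  zero <- !miss & rates == 0
  if (any(zero)) {
    warning(sum(zero), " zero rate(s) treated as missing (log undefined)")
    miss <- miss | zero
  }
  rates[miss] <- NA_real_
  dimnames(rates) <- NULL
  dimnames(miss) <- NULL
  structure(
    list(rates = rates, years = years, age_groups = ag$bounds,
         age_midpoints = ag$midpoints, missing = miss),
    class = "mortality_surface")
}

# Accepts labels ("45-49"), numeric midpoints, or a 2-column bounds table.
# Returns list(bounds = 2-col matrix (may hold NA for numeric labels),
# midpoints = numeric). Midpoint of (lo, hi) is (lo + hi) / 2.
normalize_age_groups <- function(age_groups) {
  if (is.matrix(age_groups) || is.data.frame(age_groups)) {
    b <- as.matrix(age_groups)
    if (ncol(b) != 2L) stop("age_groups table must have two columns (low, high)")
    storage.mode(b) <- "double"
    if (any(b[, 1L] >= b[, 2L])) stop("age group low bound must be below high bound")
    return(list(bounds = b, midpoints = (b[, 1L] + b[, 2L]) / 2))
  }
  labs <- as.character(age_groups)
  parsed <- lapply(labs, parse_age_label)
  bounds <- do.call(rbind, lapply(parsed, `[[`, "bounds"))
  list(bounds = bounds, midpoints = vapply(parsed, `[[`, numeric(1), "midpoint"))
}

parse_age_label <- function(lab) {
  lab <- trimws(lab)
  if (grepl("^[0-9]+\\s*[-–]\\s*[0-9]+$", lab)) {
    parts <- as.numeric(strsplit(lab, "[-–]")[[1L]])
    if (parts[1L] >= parts[2L]) {
      stop("malformed age label '", lab, "': low bound not below high bound")
    }
    return(list(bounds = parts, midpoint = (parts[1L] + parts[2L]) / 2))
  }
  num <- suppressWarnings(as.numeric(lab))
  if (is.finite(num)) return(list(bounds = c(NA_real_, NA_real_), midpoint = num))
  stop("malformed age label '", lab,
       "': expected 'lo-hi' (e.g. '45-49') or a numeric midpoint")
}

#' Read a mortality surface from CSV
#'
#' Three dialects are supported. \code{wide_age_rows}: first column
#' \code{age_group}, remaining headers are calendar years, one row per age
#' group. \code{wide_year_rows}: first column \code{year}, remaining headers
#' are age-group labels. \code{long}: columns \code{year,age_group,rate}.
#' Rows/columns may arrive in any order; the result is normalized to
#' increasing age and year. Empty cells and \code{NA} encode missing values;
#' zero rates are converted to missing with a warning.
#'
#' @param path path to a CSV file.
#' @param dialect one of \code{"wide_age_rows"}, \code{"wide_year_rows"},
#'   \code{"long"}.
#' @return a \code{\link{mortality_surface}}.
#' @export
read_surface <- function(path,
                         dialect = c("wide_age_rows", "wide_year_rows", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  if (dialect == "long") {
    need <- c("year", "age_group", "rate")
    if (!all(need %in% names(df))) {
      stop("long dialect requires columns year, age_group, rate")
    }
    years <- sort(unique(as.integer(df$year)))
    labs <- unique(as.character(df$age_group))
    mids <- vapply(labs, function(l) parse_age_label(l)$midpoint, numeric(1))
    labs <- labs[order(mids)]
    rates <- matrix(NA_real_, length(years), length(labs),
                    dimnames = list(years, labs))
    rates[cbind(match(as.integer(df$year), years),
                match(as.character(df$age_group), labs))] <- as.numeric(df$rate)
    return(mortality_surface(rates, years, labs))
  }
  if (dialect == "wide_age_rows") {
    labs <- as.character(df[[1L]])
    yr_raw <- names(df)[-1L]
    years <- suppressWarnings(as.integer(yr_raw))
    if (anyNA(years)) stop("malformed year header '", yr_raw[which(is.na(years))[1L]], "'")
    rates <- t(as.matrix(df[, -1L, drop = FALSE]))
  } else {
    years <- suppressWarnings(as.integer(df[[1L]]))
    if (anyNA(years)) stop("malformed year value in first column")
    labs <- names(df)[-1L]
    rates <- as.matrix(df[, -1L, drop = FALSE])
  }
  storage.mode(rates) <- "double"
  mids <- vapply(labs, function(l) parse_age_label(l)$midpoint, numeric(1))
  ord_a <- order(mids)
  ord_y <- order(years)
  if (is.unsorted(years[ord_y], strictly = TRUE) || any(diff(years[ord_y]) != 1L)) {
    stop("years are not contiguous: ", paste(range(years), collapse = ".."))
  }
  mortality_surface(rates[ord_y, ord_a, drop = FALSE], years[ord_y], labs[ord_a])
}

#' Write a mortality surface to CSV
#'
#' Inverse of \code{\link{read_surface}}; any of the three dialects can be
#' written, and \code{read_surface(write_surface(s))} reproduces \code{s}.
#' Missing cells are written as empty fields.
#'
#' @param s a \code{\link{mortality_surface}}.
#' @param path output CSV path.
#' @param dialect CSV dialect (see \code{\link{read_surface}}).
#' @return invisibly \code{path}.
#' @export
write_surface <- function(s, path,
                          dialect = c("wide_age_rows", "wide_year_rows",
                                      "long")) {
  stopifnot(inherits(s, "mortality_surface"))
  dialect <- match.arg(dialect)
  labs <- if (all(is.finite(s$age_groups))) {
    paste0(s$age_groups[, 1L], "-", s$age_groups[, 2L])
  } else as.character(s$age_midpoints)
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 12, format = "g"))
  if (dialect == "long") {
    df <- data.frame(year = rep(s$years, times = length(labs)),
                     age_group = rep(labs, each = length(s$years)),
                     rate = fmt(as.vector(s$rates)))
  } else if (dialect == "wide_age_rows") {
    df <- data.frame(age_group = labs, check.names = FALSE)
    for (i in seq_along(s$years)) df[[as.character(s$years[i])]] <- fmt(s$rates[i, ])
  } else {
    df <- data.frame(year = s$years, check.names = FALSE)
    for (j in seq_along(labs)) df[[labs[j]]] <- fmt(s$rates[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log-transform a mortality surface
#'
#' Takes the natural log of each rate (on the per-100,000 scale) at each age
#' midpoint for each year. Missingness (including former zero rates) is
#' propagated.
#'
#' @param s a \code{\link{mortality_surface}}.
#' @return an object of class \code{log_rate_matrix} with fields
#'   \code{logrates} (T x A), \code{years}, \code{age_midpoints},
#'   \code{missing}, \code{rate_unit} (100000).
#' @export
log_transform <- function(s) {
  stopifnot(inherits(s, "mortality_surface"))
  lr <- log(s$rates)
  lr[s$missing] <- NA_real_
  structure(
    list(logrates = lr, years = s$years, age_midpoints = s$age_midpoints,
         missing = s$missing, rate_unit = 1e5),
    class = "log_rate_matrix")
}

#' Write a curve forecast to CSV
#'
#' Writes the age-group view of a forecast as long CSV with columns
#' \code{year, age, point_rate, lower, upper, level}, rates back-transformed
#' to deaths per 100,000. Values are written with 12 significant digits so the
#' file round-trips through \code{\link{read_forecast}}.
#'
#' @param path output file path.
#' @param f a \code{curve_forecast} (see \code{\link{forecast_surface}}).
#' @return invisibly, the written data frame.
#' @export
write_forecast <- function(path, f) {
  stopifnot(inherits(f, "curve_forecast"))
  v <- f$age_group_view
  if (is.null(v)) stop("forecast has no age-group view")
  h <- length(f$years)
  a <- length(v$midpoints)
  df <- data.frame(
    year = rep(f$years, each = a),
    age = rep(v$midpoints, times = h),
    point_rate = as.vector(t(v$mean_rate)),
    lower = as.vector(t(v$lower_rate)),
    upper = as.vector(t(v$upper_rate)),
    level = f$level)
  out <- df
  for (cl in c("age", "point_rate", "lower", "upper", "level")) {
    out[[cl]] <- formatC(df[[cl]], digits = 12, format = "g")
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write forecast to '", path, "': ",
                             conditionMessage(e)))
  invisible(df)
}

#' Read a forecast CSV written by \code{\link{write_forecast}}
#'
#' @param path path to the CSV.
#' @return data frame with columns year, age, point_rate, lower, upper, level.
#' @export
read_forecast <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("year", "age", "point_rate", "lower", "upper", "level")
  if (!all(need %in% names(df))) stop("not a forecast CSV: missing columns")
  df
}

#' @export
print.mortality_surface <- function(x, ...) {
  cat("Mortality surface:", length(x$years), "years (",
      min(x$years), "-", max(x$years), "), ",
      length(x$age_midpoints), "age groups, ",
      sum(x$missing), "missing cells\n")
  invisible(x)
}

#' @export
print.log_rate_matrix <- function(x, ...) {
  cat("Log mortality rates:", length(x$years), "years x",
      length(x$age_midpoints), "ages (log deaths per 100,000)\n")
  invisible(x)
}
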