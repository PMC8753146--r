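#' Read and validate a country-index table
#'
#' Parses a CSV of country-level democracy/corruption indicators into the
#' documented schema. Recognized columns are \code{country}, \code{iso3},
#' \code{democracy_index} (0-10), \code{cpi} (0-100), \code{freedom_score}
#' (0-100), \code{control_of_corruption} (approximately -2.5 to 2.5;
#' validated against [-3, 3]), \code{turnout_avg} (percent, 0-100),
#' \code{gdp_pc} (>= 0), \code{eu_member} (0/1) and \code{population}
#' (> 0). Unknown columns are ignored; missing cells become \code{NA};
#' out-of-range values raise an error naming the row and column.
#'
#' @param path Path to a CSV file with a header row.
#' @return Data frame of class \code{"country_table"}, one row per country.
#' @export
read_country_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed CSV '", path, "': ",
                                          conditionMessage(e)))
  validate_country_table(df, path)
}

country_schema <- function() {
  list(democracy_index = c(0, 10), cpi = c(0, 100),
       freedom_score = c(0, 100), control_of_corruption = c(-3, 3),
       turnout_avg = c(0, 100), gdp_pc = c(0, Inf), eu_member = c(0, 1),
       population = c(0, Inf))
}

validate_country_table <- function(df, label = "country table") {
  schema <- country_schema()
  keep <- intersect(c("country", "iso3", names(schema)), names(df))
  df <- df[, keep, drop = FALSE]
  for (col in intersect(names(schema), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad_parse <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
    if (length(bad_parse))
      stop("non-numeric value in '", label, "', row ", bad_parse[1],
           ", column '", col, "': ", df[[col]][bad_parse[1]])
    rng <- schema[[col]]
    bad <- which(!is.na(v) & (v < rng[1] | v > rng[2]))
    if (length(bad))
      stop("out-of-range value in '", label, "', row ", bad[1],
           ", column '", col, "': ", v[bad[1]], " not in [",
           rng[1], ", ", rng[2], "]")
    df[[col]] <- v
  }
  class(df) <- c("country_table", "data.frame")
  df
}

#' @rdname read_country_table
#' @param df A country table (data frame in the documented schema).
#' @param path Destination CSV path.
#' @export
write_country_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.country_table <- function(x, ...) {
  cat("Country table:", nrow(x), "countries,", ncol(x), "fields\n")
  NextMethod()
}
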