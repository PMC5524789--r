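RECORD_COLUMNS <- c("block", "panel", "plate", "treatment",
                    "survived", "size", "fecundity", "density")

# format a numeric for CSV so that reading it back reproduces the double
# bit-for-bit; NA becomes an empty field
fmt_field <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(is.na(x), "", vapply(x, function(v) sprintf("%.17g", v), ""))
    # trim integer-valued doubles to plain integers for readability
    out <- sub("\\.0+$", "", out)
    out
  } else {
    ifelse(is.na(x), "", as.character(x))
  }
}

#' Write individual records to CSV
#'
#' Fixed header `block,panel,plate,treatment,survived,size,fecundity,density`;
#' missing values are empty fields (never sentinel numbers); numeric fields
#' are written with enough digits that [read_records()] round-trips them
#' bit-identically.
#'
#' @param records Records data.frame (extra columns are dropped).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0)
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  fields <- lapply(RECORD_COLUMNS, function(cl) fmt_field(records[[cl]]))
  lines <- c(paste(RECORD_COLUMNS, collapse = ","),
             if (nrow(records) > 0) do.call(paste, c(fields, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

parse_error <- function(line, msg) {
  stop(sprintf("parse error at line %d: %s", line, msg), call. = FALSE)
}

#' Read individual records from CSV
#'
#' Inverse of [write_records()]. Validates the header, that `survived` is
#' binary (0/1), that counts are non-negative integers, and (optionally) that
#' treatment labels belong to a known set. Errors name the offending line
#' (line 1 is the header).
#'
#' @param path CSV file path.
#' @param treatments Optional character vector of allowed treatment labels.
#' @return Records data.frame with the canonical column types.
#' @export
read_records <- function(path, treatments = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path)
  if (length(raw) == 0) stop("parse error at line 1: empty file, header required",
                             call. = FALSE)
  header <- strsplit(raw[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, RECORD_COLUMNS))
    parse_error(1, paste0("header must be '",
                          paste(RECORD_COLUMNS, collapse = ","), "'"))
  n <- length(raw) - 1L
  out <- data.frame(block = integer(n), panel = character(n),
                    plate = character(n), treatment = character(n),
                    survived = integer(n), size = integer(n),
                    fecundity = numeric(n), density = integer(n),
                    stringsAsFactors = FALSE)
  num_or_na <- function(s, line, what) {
    if (s == "") return(NA_real_)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) parse_error(line, paste0("non-numeric ", what, ": '", s, "'"))
    v
  }
  count_or_na <- function(s, line, what) {
    v <- num_or_na(s, line, what)
    if (!is.na(v) && (v < 0 || v != round(v)))
      parse_error(line, paste0(what, " must be a non-negative integer, got '",
                               s, "'"))
    as.integer(v)
  }
  for (i in seq_len(n)) {
    line <- i + 1L
    f <- strsplit(raw[line], ",", fixed = TRUE)[[1]]
    # trailing empty fields are dropped by strsplit; pad them back
    length(f) <- length(RECORD_COLUMNS)
    f[is.na(f)] <- ""
    if (!nzchar(f[4])) parse_error(line, "empty treatment label")
    if (!is.null(treatments) && !(f[4] %in% treatments))
      parse_error(line, paste0("unknown treatment label '", f[4], "'"))
    s <- count_or_na(f[5], line, "survived")
    if (!is.na(s) && !(s %in% c(0L, 1L)))
      parse_error(line, paste0("survived must be 0 or 1, got '", f[5], "'"))
    out$block[i] <- count_or_na(f[1], line, "block")
    out$panel[i] <- f[2]
    out$plate[i] <- f[3]
    out$treatment[i] <- f[4]
    out$survived[i] <- s
    out$size[i] <- count_or_na(f[6], line, "size")
    out$fecundity[i] <- num_or_na(f[7], line, "fecundity")
    out$density[i] <- count_or_na(f[8], line, "density")
  }
  out
}

#' Write / read a run configuration
#'
#' Configurations are nested key-value lists serialized as JSON; the
#' round-trip is lossless for the fields used by the pipeline.
#'
#' @param config A [run_config()] list.
#' @param path File path.
#' @return `read_config()` returns the configuration list.
#' @export
write_config <- function(config, path) {
  config <- unclass(config)
  # named numeric vectors lose their names as JSON arrays; store the
  # coefficient maps as objects instead
  if (!is.null(config$generator)) {
    for (f in c("beta_treatment", "beta_panel", "size_log_mean",
                "fecundity_mu")) {
      if (!is.null(config$generator[[f]]))
        config$generator[[f]] <- as.list(config$generator[[f]])
    }
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite reads named vectors back as lists in some shapes; normalise the
  # generator coefficient maps to named numeric vectors
  if (!is.null(cfg$generator)) {
    for (f in c("beta_treatment", "beta_panel", "size_log_mean",
                "fecundity_mu")) {
      if (!is.null(cfg$generator[[f]]))
        cfg$generator[[f]] <- unlist(cfg$generator[[f]])
    }
  }
  cfg
}
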