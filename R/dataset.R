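#' Read and validate a challenge-test dataset
#'
#' The package's event-record dialect is a plain CSV with a fixed header,
#' one row per dose event or observation:
#'
#' * `STUDY` - study identifier (text).
#' * `ID` - subject number (positive integer, unique across studies).
#' * `OCC` - occasion index (1-based study day within subject).
#' * `TRT` - 0 placebo occasion, 1 treatment occasion.
#' * `EVID` - 1 dose event, 0 observation.
#' * `AMT` - dose (mg), dose rows only.
#' * `TAD` - time after (possibly placebo) administration (h).
#' * `CLOCK` - clock time of day (decimal h, in [0, 24)).
#' * `DVID` - observation type: 1 plasma 5-HTP (ng/mL), 2 total serum
#'   cortisol (ng/mL), 3 saliva cortisol (nmol/L).
#' * `DV` - observation value.
#' * `CBG` - subject CBG (mg/L), constant within subject.
#' * `MDV` - 1 if `DV` is missing.
#'
#' @param path File to read.
#' @return Validated tibble.
#' @export
read_challenge_dataset <- function(path) {
  if (!file.exists(path)) {
    stop("No such file: ", path, call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  required <- c("STUDY", "ID", "OCC", "TRT", "EVID", "AMT", "TAD",
                "CLOCK", "DVID", "DV", "CBG", "MDV")
  if (!all(required %in% header)) {
    stop("File header is missing column(s): ",
         paste(setdiff(required, header), collapse = ", "),
         call. = FALSE)
  }
  d <- readr::read_csv(
    path,
    col_types = readr::cols(
      STUDY = readr::col_character(), ID = readr::col_integer(),
      OCC = readr::col_integer(), TRT = readr::col_integer(),
      EVID = readr::col_integer(), AMT = readr::col_double(),
      TAD = readr::col_double(), CLOCK = readr::col_double(),
      DVID = readr::col_integer(), DV = readr::col_double(),
      CBG = readr::col_double(), MDV = readr::col_integer()
    ),
    progress = FALSE
  )
  validate_challenge_dataset(d)
}

#' @rdname read_challenge_dataset
#' @param data A dataset tibble to validate; every invariant violation is
#'   reported with its row numbers.
#' @export
validate_challenge_dataset <- function(data) {
  required <- c("STUDY", "ID", "OCC", "TRT", "EVID", "AMT", "TAD", "CLOCK",
                "DVID", "DV", "CBG", "MDV")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("Dataset is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, paste0(
        msg, " (row", if (length(rows) > 1) "s", " ",
        paste(utils::head(rows, 10), collapse = ", "),
        if (length(rows) > 10) ", ...", ")"))
    }
  }
  obs <- data$EVID == 0L
  flag(!data$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  flag(obs & !data$DVID %in% c(1L, 2L, 3L), "unknown DVID on observation row")
  flag(obs & data$MDV == 0L & (is.na(data$DV) | data$DV < 0),
       "observation row with MDV=0 needs DV >= 0")
  flag(data$CLOCK < 0 | data$CLOCK >= 24, "CLOCK must lie in [0, 24)")
  flag(data$EVID == 1L & (is.na(data$AMT) | data$AMT <= 0),
       "dose row needs AMT > 0")
  flag(!data$TRT %in% c(0L, 1L), "TRT must be 0 or 1")
  flag(data$ID <= 0, "ID must be a positive integer")
  if (nrow(data) == 0) {
    if (length(problems)) {
      stop("Invalid challenge dataset:\n  - ",
           paste(problems, collapse = "\n  - "), call. = FALSE)
    }
    return(tibble::as_tibble(data))
  }
  # every treatment occasion must carry exactly one dose row
  occ_tab <- dplyr::summarise(
    dplyr::group_by(data, .data$ID, .data$OCC),
    trt = max(.data$TRT), n_dose = sum(.data$EVID == 1L), .groups = "drop")
  bad_occ <- occ_tab[occ_tab$trt == 1L & occ_tab$n_dose != 1L, ]
  if (nrow(bad_occ)) {
    problems <- c(problems, paste0(
      "treatment occasion without exactly one dose row: subject ",
      paste(paste0(bad_occ$ID, "/occ", bad_occ$OCC), collapse = ", ")))
  }
  cbg_tab <- dplyr::summarise(dplyr::group_by(data, .data$ID),
                              n_cbg = dplyr::n_distinct(.data$CBG),
                              .groups = "drop")
  if (any(cbg_tab$n_cbg > 1)) {
    problems <- c(problems, paste0(
      "CBG varies within subject ",
      paste(cbg_tab$ID[cbg_tab$n_cbg > 1], collapse = ", ")))
  }
  if (length(problems)) {
    stop("Invalid challenge dataset:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Write a challenge dataset as byte-stable CSV
#'
#' Deterministic column order and fixed decimal formatting (C locale,
#' no scientific notation), so the same dataset always serialises to the
#' same bytes.
#'
#' @param data A validated dataset tibble.
#' @param path Output file.
#' @param digits Decimal places used for floating-point columns.
#' @return `path`, invisibly.
#' @export
write_challenge_dataset <- function(data, path, digits = 6) {
  data <- validate_challenge_dataset(data)
  cols <- c("STUDY", "ID", "OCC", "TRT", "EVID", "AMT", "TAD", "CLOCK",
            "DVID", "DV", "CBG", "MDV")
  fmt_num <- function(x) {
    out <- formatC(x, format = "f", digits = digits, drop0trailing = TRUE,
                   decimal.mark = ".")
    out[is.na(x)] <- ""
    out
  }
  fmt_int <- function(x) {
    out <- formatC(x, format = "d")
    out[is.na(x)] <- ""
    out
  }
  d <- data[, cols]
  body <- cbind(
    STUDY = as.character(d$STUDY), ID = fmt_int(d$ID), OCC = fmt_int(d$OCC),
    TRT = fmt_int(d$TRT), EVID = fmt_int(d$EVID), AMT = fmt_num(d$AMT),
    TAD = fmt_num(d$TAD), CLOCK = fmt_num(d$CLOCK), DVID = fmt_int(d$DVID),
    DV = fmt_num(d$DV), CBG = fmt_num(d$CBG), MDV = fmt_int(d$MDV)
  )
  lines <- paste(cols, collapse = ",")
  if (nrow(d) > 0) {
    lines <- c(lines, apply(body, 1, paste, collapse = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
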