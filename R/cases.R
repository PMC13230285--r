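#' Incident-case records: construction, validation and CSV round trip
#'
#' A case record is one diagnosed cancer as seen in a register: disease
#' type (`"dcis"`/`"invasive"`), detection mode (`"screen"`/
#' `"symptomatic"`), size at detection in mm (lesion maximum diameter for
#' DCIS, tumour diameter for invasive cancer), calendar detection time, and
#' the calendar times of all attended screens up to and including detection.
#' For a screen-detected case the last screen time must equal the detection
#' time (all earlier screens were negative); for a symptomatic case all
#' screens were negative.
#'
#' The CSV schema is `case_id, disease_type, detection_mode, size_mm,
#' detection_time, screen_times`, with `screen_times` a semicolon-joined
#' list of decimal years (UTF-8, header required).
#'
#' @param cases an `nh_cases` data frame (see [sample_case_dataset()]).
#' @param params an [nh_params()] object (for the size floors `l0`,
#'   `diameter(v0)`).
#' @return `validate_cases()` returns the cases invisibly or fails with the
#'   offending row numbers.
#' @export
validate_cases <- function(cases, params = nh_params()) {
  need <- c("case_id", "disease_type", "detection_mode", "size_mm",
            "detection_time", "screen_times")
  miss <- setdiff(need, names(cases))
  if (length(miss))
    stop("case table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- function(cond, what) {
    if (any(cond))
      stop("invalid case record(s) [row ", paste(utils::head(which(cond), 5),
                                                 collapse = ", "), "]: ", what)
  }
  bad(!cases$disease_type %in% c("dcis", "invasive"),
      "disease_type must be 'dcis' or 'invasive'")
  bad(!cases$detection_mode %in% c("screen", "symptomatic"),
      "detection_mode must be 'screen' or 'symptomatic'")
  d0 <- diameter_from_volume(params$v0)
  floor_mm <- ifelse(cases$disease_type == "dcis", params$l0, d0)
  bad(!(cases$size_mm > floor_mm),
      "size_mm must exceed the size floor (l0 / diameter(v0))")
  stl <- cases$screen_times
  sorted_ok <- vapply(stl, function(s)
    length(s) == 0 || all(diff(s) > 0), logical(1))
  bad(!sorted_ok, "screen_times must be strictly increasing")
  within_ok <- mapply(function(s, dt) length(s) == 0 || max(s) <= dt + 1e-6,
                      stl, cases$detection_time)
  bad(!within_ok, "screen_times must not exceed detection_time")
  scr_ok <- mapply(function(s, dt, mode)
    mode != "screen" || (length(s) > 0 && abs(max(s) - dt) <= 1e-6),
    stl, cases$detection_time, cases$detection_mode)
  bad(!scr_ok,
      "screen-detected cases must have their last screen at detection_time")
  invisible(cases)
}

#' @rdname validate_cases
#' @param path CSV file path.
#' @export
write_cases <- function(cases, path, params = nh_params()) {
  validate_cases(cases, params)
  flat <- data.frame(case_id = cases$case_id,
                     disease_type = cases$disease_type,
                     detection_mode = cases$detection_mode,
                     size_mm = cases$size_mm,
                     detection_time = cases$detection_time,
                     screen_times = vapply(cases$screen_times, function(s)
                       paste(format(s, digits = 15, trim = TRUE,
                                    scientific = FALSE), collapse = ";"),
                       character(1)))
  utils::write.csv(flat, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname validate_cases
#' @export
read_cases <- function(path, params = nh_params()) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("case_id", "disease_type", "detection_mode", "size_mm",
            "detection_time", "screen_times")
  miss <- setdiff(need, names(flat))
  if (length(miss))
    stop("case CSV lacks column(s): ", paste(miss, collapse = ", "))
  parse_row <- function(i) {
    s <- flat$screen_times[i]
    if (is.na(s) || !nzchar(s)) return(numeric())
    out <- suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
    if (anyNA(out))
      stop("malformed screen_times at data row ", i, ": '", s, "'")
    out
  }
  cases <- flat[need[need != "screen_times"]]
  cases$screen_times <- lapply(seq_len(nrow(flat)), parse_row)
  class(cases) <- c("nh_cases", "data.frame")
  validate_cases(cases, params)
  cases
}
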