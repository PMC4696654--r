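#' Read and write time courses and isotherms as CSV
#'
#' Plain comma-separated files with '.' decimal marks.  Time courses use
#' the header `time_s,m00_uM,m10_uM,m01_uM,m11_uM,l_uM,n_avg`; isotherms
#' use `free_l_uM,n_avg`.
#'
#' @param tc a `binding_timecourse`.
#' @param iso a [isotherm()].
#' @param path file path.
#' @return The written path (write functions, invisibly); a data frame
#'   (`read_timecourse_csv`) or a [isotherm()] (`read_isotherm_csv`).
#' @name binding_io
NULL

#' @rdname binding_io
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "binding_timecourse"))
  df <- tc$states
  out <- data.frame(time_s = df$t, m00_uM = df$m00, m10_uM = df$m10,
                    m01_uM = df$m01, m11_uM = df$m11, l_uM = df$l,
                    n_avg = binding_density(tc))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname binding_io
#' @export
read_timecourse_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "m00_uM", "m10_uM", "m01_uM", "m11_uM", "l_uM")
  if (!all(need %in% names(df)))
    stop("time-course CSV must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname binding_io
#' @export
write_isotherm_csv <- function(iso, path) {
  stopifnot(inherits(iso, "binding_isotherm"))
  write.csv(data.frame(free_l_uM = iso$free_l, n_avg = iso$n_avg),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname binding_io
#' @export
read_isotherm_csv <- function(path, validate = TRUE) {
  df <- read.csv(path)
  if (!all(c("free_l_uM", "n_avg") %in% names(df)))
    stop("isotherm CSV must have columns free_l_uM, n_avg")
  isotherm(df$free_l_uM, df$n_avg, provenance = list(source = path),
           validate = validate)
}

#' @rdname binding_io
#' @param validate passed to [isotherm()]; disable for noisy data.
NULL
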