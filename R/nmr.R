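#' Estimate butyrate isotopomer class fractions from HMBC cross-peak integrals
#'
#' Implements the split/non-split HMBC correction. Four cross-peak integrals
#' are observed for butyrate: at H-2 the correlation to C-4 (non-split when
#' C-2 is not enriched, split by the one-bond coupling when it is), and at
#' H-4 the correlation to C-2 (likewise split when C-4 is enriched). The two
#' split peaks measure the same doubly labelled population, so their ratio
#' `f = h2c4_split / h4c2_split` is the factor that equalizes the two proton
#' sides; multiplying the H-4-side non-split integral by `f` puts all three
#' populations on a common scale, from which the fractions of
#' [2-13C]-, [4-13C]- and [2,4-13C]butyrate follow.
#'
#' When both split integrals are zero but non-split signal exists, there is
#' no doubly labelled population to calibrate on; fractions are computed with
#' `f = 1` and flagged (`calibrated = FALSE`).
#'
#' @param integrals Data frame with columns `h2c4_nonsplit`, `h2c4_split`,
#'   `h4c2_nonsplit`, `h4c2_split` (one row per experiment; any other
#'   columns, e.g. an experiment id, are carried through), or a named numeric
#'   vector for a single experiment. All integrals must be non-negative.
#' @return A tibble with the input identifier columns plus `p2`, `p4`, `p24`
#'   (fractions of labelled butyrate, summing to 1), the equalization factor
#'   `f`, and `calibrated`.
#' @examples
#' estimate_butyrate_fractions(
#'   c(h2c4_nonsplit = 7.1, h2c4_split = 1.6,
#'     h4c2_nonsplit = 1.3, h4c2_split = 1.6))
#' @export
estimate_butyrate_fractions <- function(integrals) {
  cols <- c("h2c4_nonsplit", "h2c4_split", "h4c2_nonsplit", "h4c2_split")
  if (!is.data.frame(integrals)) {
    stopifnot(all(cols %in% names(integrals)))
    integrals <- tibble::as_tibble(as.list(integrals[cols]))
  }
  stopifnot(all(cols %in% names(integrals)))
  out <- purrr::pmap_dfr(integrals[cols], estimate_fractions_one)
  dplyr::bind_cols(
    integrals[setdiff(names(integrals), c(cols, names(out)))],
    tibble::as_tibble(integrals[cols]),
    out
  )
}

estimate_fractions_one <- function(h2c4_nonsplit, h2c4_split,
                                   h4c2_nonsplit, h4c2_split) {
  vals <- c(h2c4_nonsplit, h2c4_split, h4c2_nonsplit, h4c2_split)
  if (any(vals < 0)) stop("integrals must be >= 0", call. = FALSE)
  if (all(vals <= 0)) {
    stop("all four integrals are zero: fractions undefined", call. = FALSE)
  }
  if (h4c2_split > 0) {
    f <- h2c4_split / h4c2_split
    calibrated <- TRUE
  } else if (h2c4_split <= 0) {
    # no doubly labelled population: nothing to calibrate on
    f <- 1
    calibrated <- FALSE
  } else {
    stop("h2c4_split > 0 but h4c2_split == 0: inconsistent integrals ",
         "(both split peaks measure the same [2,4-13C] population)",
         call. = FALSE)
  }
  corrected_h4c2 <- f * h4c2_nonsplit
  s <- h2c4_nonsplit + h2c4_split + corrected_h4c2
  if (s <= 0) {
    stop("zero total corrected signal: fractions undefined", call. = FALSE)
  }
  tibble::tibble(
    p2 = corrected_h4c2 / s,
    p4 = h2c4_nonsplit / s,
    p24 = h2c4_split / s,
    f = f,
    calibrated = calibrated
  )
}

#' Read an HMBC integral table from CSV
#'
#' Expects columns `experiment_id`, `h2c4_nonsplit`, `h2c4_split`,
#' `h4c2_nonsplit`, `h4c2_split`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_hmbc_integrals <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("h2c4_nonsplit", "h2c4_split", "h4c2_nonsplit", "h4c2_split")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("HMBC integral table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Reference 13C chemical-shift table
#'
#' The packaged shift table for the compounds relevant to lysine
#' fermentation: lysine C-6 (41.75 p.p.m.) and C-2 (57.19), butyrate C-2
#' (42.33) and C-4 (15.95), acetate C-2 (25.99).
#'
#' @param path Optional CSV with columns `compound`, `position`, `shift_ppm`
#'   to replace the packaged table.
#' @return Tibble with columns `compound`, `position`, `shift_ppm`.
#' @examples
#' shift_table()
#' @export
shift_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chemical_shifts.csv",
                        package = "butyrtrace", mustWork = TRUE)
  }
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("compound", "position", "shift_ppm") %in% names(tb)),
            all(tb$shift_ppm > 0),
            !anyDuplicated(tb[, c("compound", "position")]))
  tb
}

#' Assign 1-D 13C peaks to compounds by chemical shift
#'
#' Matches each observed shift to the reference entry within `tol` p.p.m.
#' If several entries fall within the tolerance the nearest is returned and
#' the assignment is flagged ambiguous; if none does, the peak is unassigned.
#'
#' @param shifts Numeric vector of observed shifts (p.p.m.).
#' @param table Reference table from [shift_table()].
#' @param tol Matching tolerance in p.p.m. (> 0).
#' @return Tibble with one row per input shift: `shift_ppm`, `compound`,
#'   `position` (NA when unassigned), `delta_ppm`, `ambiguous`.
#' @examples
#' assign_peaks(c(15.95, 42.0, 100.0), tol = 0.5)
#' @export
assign_peaks <- function(shifts, table = shift_table(), tol = 0.2) {
  stopifnot(is.numeric(shifts), tol > 0)
  purrr::map_dfr(shifts, function(s) {
    d <- abs(table$shift_ppm - s)
    within <- which(d <= tol)
    if (length(within) == 0) {
      return(tibble::tibble(shift_ppm = s, compound = NA_character_,
                            position = NA_integer_, delta_ppm = NA_real_,
                            ambiguous = FALSE))
    }
    best <- within[which.min(d[within])]
    tibble::tibble(shift_ppm = s, compound = table$compound[best],
                   position = as.integer(table$position[best]),
                   delta_ppm = d[best], ambiguous = length(within) > 1)
  })
}
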