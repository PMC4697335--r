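#' Parse a molecular formula over C, H, O, N
#'
#' Parses formula strings such as `"C6H14O2N2"` into exact integer element
#' counts. The element alphabet is fixed to carbon, hydrogen, oxygen and
#' nitrogen: the fermentation equations analysed by this package are written
#' over free acids, so phosphorus and sulfur (CoA, phosphoryl moieties) never
#' appear; acyl-CoA species are represented by their acyl carbon skeletons.
#'
#' @param formula Character vector of molecular formulas, e.g.
#'   `c("C6H14O2N2", "H2O")`. An element symbol may be followed by an optional
#'   positive integer count (absent count = 1).
#'
#' @return A tibble with one row per input formula and integer columns
#'   `C`, `H`, `O`, `N` (absent elements are 0), plus the input string in
#'   column `formula`.
#'
#' @examples
#' parse_formula(c("C6H14O2N2", "H2O", "C12H24O7N2"))
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) >= 1)
  rows <- purrr::map(formula, parse_formula_one)
  dplyr::bind_cols(tibble::tibble(formula = formula), dplyr::bind_rows(rows))
}

# single formula -> named integer vector c(C=,H=,O=,N=)
parse_formula_one <- function(x) {
  if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x)) {
    stop("formula must be a non-empty string", call. = FALSE)
  }
  counts <- c(C = 0L, H = 0L, O = 0L, N = 0L)
  tokens <- regmatches(x, gregexpr("[A-Za-z][a-z]*[0-9]*", x))[[1]]
  if (sum(nchar(tokens)) != nchar(x)) {
    bad <- substr(gsub(paste(tokens, collapse = "|"), "", x), 1, 5)
    stop("malformed formula '", x, "': unparseable token near '", bad, "'",
         call. = FALSE)
  }
  for (tok in tokens) {
    elem <- sub("[0-9]*$", "", tok)
    if (!elem %in% names(counts)) {
      stop("unsupported element '", elem, "' in formula '", x,
           "' (allowed: C, H, O, N)", call. = FALSE)
    }
    digits <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(digits)) as.integer(digits) else 1L
    if (is.na(n) || n <= 0L) {
      stop("invalid count in token '", tok, "' of formula '", x, "'",
           call. = FALSE)
    }
    counts[elem] <- counts[elem] + n
  }
  tibble::as_tibble(as.list(counts))
}

#' Count carbon atoms in a formula
#'
#' @param formula Character vector of molecular formulas.
#' @return Integer vector of carbon counts.
#' @examples
#' n_carbons("C4H8O2")
#' @export
n_carbons <- function(formula) {
  parse_formula(formula)$C
}
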