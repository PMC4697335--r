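#' Build a fermentation equation from explicit coefficients
#'
#' Constructs a `fermentation_equation` object from named coefficient vectors
#' without solving anything. Useful for checking a proposed equation with
#' [check_balance()].
#'
#' @param substrates,products Named numeric vectors: names are metabolite
#'   names (resolved against `metabolites`) or raw formulas, values are
#'   stoichiometric coefficients (> 0).
#' @param metabolites Lookup tibble with columns `name` and `formula`;
#'   defaults to the metabolites of the packaged pathway definition.
#'
#' @return A `fermentation_equation` object: a list with a `species` tibble
#'   (`name`, `formula`, `role`, `coefficient`, element counts) and metadata.
#'
#' @examples
#' eq <- as_equation(c(lysine = 1, water = 2),
#'                   c(butyrate = 1, acetate = 1, ammonia = 2))
#' check_balance(eq)
#' @export
as_equation <- function(substrates, products,
                        metabolites = default_metabolites()) {
  species <- dplyr::bind_rows(
    resolve_species(substrates, "substrate", metabolites),
    resolve_species(products, "product", metabolites)
  )
  if (any(species$coefficient < 0)) {
    stop("stoichiometric coefficients must be >= 0", call. = FALSE)
  }
  structure(
    list(species = species, dimension = NA_integer_,
         reference = NA_character_),
    class = "fermentation_equation"
  )
}

resolve_species <- function(x, role, metabolites) {
  if (length(x) == 0) {
    return(tibble::tibble(name = character(), formula = character(),
                          role = character(), coefficient = numeric(),
                          C = integer(), H = integer(), O = integer(),
                          N = integer()))
  }
  if (is.character(x)) {
    nm <- x
    coefs <- rep(NA_real_, length(x))
  } else {
    stopifnot(!is.null(names(x)))
    nm <- names(x)
    coefs <- unname(x)
  }
  formulas <- purrr::map_chr(nm, function(n) {
    hit <- metabolites$formula[metabolites$name == n]
    if (length(hit) == 1) hit else n  # fall back to treating the name as a formula
  })
  counts <- parse_formula(formulas)
  tibble::tibble(name = nm, formula = formulas, role = role,
                 coefficient = coefs,
                 C = counts$C, H = counts$H, O = counts$O, N = counts$N)
}

#' Elemental residuals of a fermentation equation
#'
#' Computes, for each element, the signed imbalance
#' (sum over products of coefficient x count) minus
#' (sum over substrates of coefficient x count). A balanced equation has a
#' zero residual for every element.
#'
#' @param equation A `fermentation_equation`, e.g. from [as_equation()] or
#'   [balance_equation()].
#' @return A named numeric vector of residuals for `C`, `H`, `O`, `N`.
#' @examples
#' check_balance(as_equation(c(lysine = 1), c(butyrate = 1)))
#' @export
check_balance <- function(equation) {
  stopifnot(inherits(equation, "fermentation_equation"))
  sp <- equation$species
  sgn <- ifelse(sp$role == "product", 1, -1)
  res <- vapply(c("C", "H", "O", "N"),
                function(e) sum(sgn * sp$coefficient * sp[[e]]),
                numeric(1))
  res[is.na(res)] <- 0  # empty equation
  res
}

#' Balance a fermentation equation over C, H, O, N
#'
#' Solves the elemental-balance linear system for the stoichiometric
#' coefficients of a proposed fermentation, with one reference substrate
#' fixed at coefficient 1. If the solution space is zero-dimensional the
#' unique solution is returned; if it is one-dimensional (after applying any
#' `fixed` coefficients) the minimal non-negative all-integer member is
#' selected. Used to reproduce the proposed lysine and fructoselysine
#' fermentation equations of *Intestinimonas* AF211.
#'
#' @param substrates,products Character vectors of metabolite names (resolved
#'   against `metabolites`) or raw molecular formulas.
#' @param reference Name of the substrate fixed at coefficient 1. Defaults to
#'   the first substrate.
#' @param fixed Optional named numeric vector of coefficients to pin before
#'   solving (e.g. `c(acetate = 1)` for co-consumed acetate).
#' @param metabolites Lookup tibble (`name`, `formula`).
#' @param max_coefficient Bound on the integer coefficients searched for when
#'   selecting the minimal integer member of a one-dimensional family.
#'
#' @return A `fermentation_equation` with solved coefficients, the
#'   solution-space `dimension`, the `reference` species and near-zero
#'   elemental residuals. Supports [generics::tidy()], [generics::glance()]
#'   and `print()`.
#'
#' @examples
#' balance_equation(c("lysine", "water"),
#'                  c("butyrate", "acetate", "ammonia"))
#' balance_equation(c("fructoselysine", "acetate", "water"),
#'                  c("butyrate", "ammonia", "co2"),
#'                  fixed = c(acetate = 1))
#' @export
balance_equation <- function(substrates, products,
                             reference = substrates[[1]],
                             fixed = NULL,
                             metabolites = default_metabolites(),
                             max_coefficient = 50L) {
  stopifnot(is.character(substrates), is.character(products))
  if (!reference %in% substrates) {
    stop("reference '", reference, "' must be one of the substrates",
         call. = FALSE)
  }
  sp <- dplyr::bind_rows(
    resolve_species(substrates, "substrate", metabolites),
    resolve_species(products, "product", metabolites)
  )
  if (anyDuplicated(sp$name)) {
    stop("species names must be unique across substrates and products",
         call. = FALSE)
  }
  elems <- c("C", "H", "O", "N")
  # signed element matrix: products +, substrates -
  M <- t(as.matrix(sp[, elems])) * rep(ifelse(sp$role == "product", 1, -1),
                                       each = length(elems))
  colnames(M) <- sp$name

  coef <- stats::setNames(rep(NA_real_, nrow(sp)), sp$name)
  coef[reference] <- 1
  if (!is.null(fixed)) {
    unknown_fixed <- setdiff(names(fixed), sp$name)
    if (length(unknown_fixed)) {
      stop("fixed coefficients for unknown species: ",
           paste(unknown_fixed, collapse = ", "), call. = FALSE)
    }
    coef[names(fixed)] <- fixed
  }
  free <- names(coef)[is.na(coef)]
  b <- -M[, !is.na(coef), drop = FALSE] %*% coef[!is.na(coef)]
  A <- M[, free, drop = FALSE]

  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  tol <- max(dim(A)) * max(sv$d, 0) * 1e-12 + 1e-12
  rank <- sum(sv$d > tol)
  dim_null <- length(free) - rank

  # minimum-norm particular solution
  d_inv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  x0 <- sv$v[, seq_along(sv$d), drop = FALSE] %*%
    (d_inv * crossprod(sv$u[, seq_along(sv$d), drop = FALSE], b))
  x0 <- drop(x0)
  resid <- drop(A %*% x0 - b)
  if (any(abs(resid) > 1e-8)) {
    bad <- elems[abs(resid) > 1e-8]
    stop("no elemental balance exists for these species; violated element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  if (dim_null == 0) {
    sol <- x0
    if (any(sol < -1e-9)) {
      neg <- free[sol < -1e-9]
      stop("no non-negative solution: coefficient(s) of ",
           paste(neg, collapse = ", "), " would be negative", call. = FALSE)
    }
    sol <- round_clean(pmax(sol, 0))
  } else if (dim_null == 1) {
    v <- sv$v[, ncol(sv$v), drop = TRUE]
    sol <- select_integer_member(x0, v, free, coef, max_coefficient)
  } else {
    stop("solution space is ", dim_null, "-dimensional after constraints; ",
         "ambiguous balance (free directions remain among: ",
         paste(free, collapse = ", "), ")", call. = FALSE)
  }
  coef[free] <- sol

  sp$coefficient <- unname(coef[sp$name])
  out <- structure(
    list(species = sp, dimension = dim_null, reference = reference),
    class = "fermentation_equation"
  )
  out$residual <- check_balance(out)
  out
}

# one-dimensional family x(t) = x0 + t v over the free species; pick the
# minimal-total-coefficient non-negative member whose coefficients (with the
# reference fixed at 1) are all integers
select_integer_member <- function(x0, v, free, coef_fixed, max_coefficient) {
  # feasible t interval from x0 + t v >= 0
  lo <- -Inf
  hi <- Inf
  for (i in seq_along(v)) {
    if (abs(v[i]) < 1e-12) {
      if (x0[i] < -1e-9) {
        stop("no non-negative solution: coefficient of ", free[i],
             " is negative along the whole family", call. = FALSE)
      }
    } else if (v[i] > 0) {
      lo <- max(lo, -x0[i] / v[i])
    } else {
      hi <- min(hi, -x0[i] / v[i])
    }
  }
  if (lo > hi + 1e-9) {
    stop("no non-negative solution in the one-dimensional balance family",
         call. = FALSE)
  }
  # candidate t values where some free coefficient hits an integer
  cand <- unlist(lapply(seq_along(v), function(i) {
    if (abs(v[i]) < 1e-12) return(numeric())
    ms <- seq(0L, max_coefficient)
    ts <- (ms - x0[i]) / v[i]
    ts[ts >= lo - 1e-9 & ts <= hi + 1e-9]
  }))
  cand <- unique(round(cand, 10))
  ok <- purrr::keep(cand, function(t) {
    x <- x0 + t * v
    all(x >= -1e-9) && all(abs(x - round(x)) < 1e-7)
  })
  if (length(ok) == 0) {
    stop("ambiguous balance: one free direction remains (",
         paste(sprintf("%s: %+.3f", free, v), collapse = ", "),
         ") and no all-integer non-negative member was found", call. = FALSE)
  }
  sols <- lapply(ok, function(t) round_clean(pmax(x0 + t * v, 0)))
  totals <- vapply(sols, sum, numeric(1))
  sols[[which.min(totals)]]
}

round_clean <- function(x, digits = 9) {
  out <- round(x, digits)
  ints <- abs(out - round(out)) < 1e-7
  out[ints] <- round(out[ints])
  out
}

#' @export
print.fermentation_equation <- function(x, ...) {
  sp <- x$species
  fmt <- function(rows) {
    paste(sprintf("%s %s", format_coef(rows$coefficient), rows$name),
          collapse = " + ")
  }
  cat(fmt(sp[sp$role == "substrate", ]), "->",
      fmt(sp[sp$role == "product", ]), "\n")
  if (!is.na(x$dimension)) {
    cat("solution-space dimension:", x$dimension, "\n")
  }
  if (!is.null(x$residual)) {
    cat("max |elemental residual|:",
        format(max(abs(x$residual)), digits = 3), "\n")
  }
  invisible(x)
}

format_coef <- function(x) {
  ifelse(is.na(x), "?", ifelse(x == round(x), format(round(x)),
                               format(signif(x, 6))))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.fermentation_equation <- function(x, ...) {
  x$species[, c("name", "formula", "role", "coefficient")]
}

#' @exportS3Method generics::glance
glance.fermentation_equation <- function(x, ...) {
  res <- if (is.null(x$residual)) check_balance(x) else x$residual
  tibble::tibble(
    dimension = x$dimension,
    reference = x$reference,
    balanced = max(abs(res)) < 1e-8,
    max_abs_residual = max(abs(res))
  )
}
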