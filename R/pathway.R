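#' Load and validate an atom-mapped pathway model
#'
#' Reads a pathway definition (metabolites, atom-mapped reactions, branch
#' labels) from a YAML file and validates it: formulas must parse, every
#' metabolite referenced by a reaction must be declared, each reaction must
#' conserve carbon through its atom map (every substrate carbon maps to
#' exactly one product carbon and vice versa), and the terminal product must
#' be reachable from every declared substrate. The packaged default encodes
#' the two butyrogenic branches of *Intestinimonas* AF211-type metabolism:
#' the 10-step lysine pathway (cleaving lysine between C2 and C3 so carbons
#' 3-6 become butyrate) and the acetyl-CoA condensation pathway, plus the
#' fructoselysine entry steps and lactate overflow.
#'
#' @param path Path to a pathway YAML file; `NULL` loads the packaged
#'   default model.
#' @return A `pathway_model` object: list with `metabolites` (tibble of
#'   `name`, `formula`, `n_carbons`), `reactions` (named list; each reaction
#'   holds `id`, `enzyme`, `branch`, `substrates`, `products` and an
#'   `atom_map` tibble), `branch_index` (branch -> reaction ids),
#'   `substrates` and `terminal_product`.
#' @examples
#' model <- load_pathway()
#' length(model$branch_index$lysine)
#' @export
load_pathway <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathway_af211.yaml",
                        package = "butyrtrace", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    stop("unsupported pathway config schema_version", call. = FALSE)
  }
  mets <- dplyr::bind_rows(lapply(cfg$metabolites, tibble::as_tibble))
  if (anyDuplicated(mets$name)) {
    stop("duplicate metabolite names in pathway config", call. = FALSE)
  }
  counts <- parse_formula(mets$formula)
  mets$n_carbons <- counts$C
  if (any(counts$C < 0 | counts$H < 0 | counts$O < 0 | counts$N < 0)) {
    stop("negative element count in metabolite formula", call. = FALSE)
  }

  reactions <- lapply(cfg$reactions, parse_reaction, metabolites = mets)
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(names(reactions))) {
    stop("duplicate reaction ids in pathway config", call. = FALSE)
  }
  for (rx in reactions) validate_atom_map(rx, mets)

  branches <- vapply(reactions, `[[`, character(1), "branch")
  branch_index <- split(names(reactions), branches)

  model <- structure(
    list(metabolites = mets, reactions = reactions,
         branch_index = branch_index,
         substrates = cfg$substrates %||% character(),
         terminal_product = cfg$terminal_product %||% "butyrate",
         path = path),
    class = "pathway_model"
  )
  check_reachability(model)
  model
}

parse_reaction <- function(rx, metabolites) {
  side <- function(entries) {
    tb <- dplyr::bind_rows(lapply(entries, tibble::as_tibble))
    if (any(tb$coef <= 0)) {
      stop("reaction '", rx$id, "': coefficients must be > 0", call. = FALSE)
    }
    missing <- setdiff(tb$name, metabolites$name)
    if (length(missing)) {
      stop("reaction '", rx$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tb
  }
  amap <- if (length(rx$atom_map)) {
    tibble::tibble(
      substrate = vapply(rx$atom_map, function(e) as.character(e[[1]]), ""),
      sub_carbon = vapply(rx$atom_map, function(e) as.integer(e[[2]]), 0L),
      product = vapply(rx$atom_map, function(e) as.character(e[[3]]), ""),
      prod_carbon = vapply(rx$atom_map, function(e) as.integer(e[[4]]), 0L)
    )
  } else {
    tibble::tibble(substrate = character(), sub_carbon = integer(),
                   product = character(), prod_carbon = integer())
  }
  list(id = rx$id, enzyme = rx$enzyme %||% "", branch = rx$branch,
       substrates = side(rx$substrates), products = side(rx$products),
       atom_map = amap)
}

# carbon conservation: every carbon slot (index 1..coef*n_carbons) of every
# carbon-bearing species is mapped exactly once on each side
validate_atom_map <- function(rx, metabolites) {
  ncar <- stats::setNames(metabolites$n_carbons, metabolites$name)
  check_side <- function(side_tb, col_name, col_carbon, side_label) {
    for (i in seq_len(nrow(side_tb))) {
      nm <- side_tb$name[i]
      slots <- side_tb$coef[i] * ncar[[nm]]
      if (slots == 0) next
      mapped <- rx$atom_map[[col_carbon]][rx$atom_map[[col_name]] == nm]
      if (length(mapped) != slots || !setequal(mapped, seq_len(slots)) ||
          anyDuplicated(mapped)) {
        missing_idx <- setdiff(seq_len(slots), mapped)
        dup_idx <- unique(mapped[duplicated(mapped)])
        bad <- c(missing_idx, dup_idx,
                 setdiff(unique(mapped), seq_len(slots)))
        stop("reaction '", rx$id, "': atom map does not conserve carbon for ",
             side_label, " '", nm, "' (carbon index ",
             paste(bad, collapse = ", "), ")", call. = FALSE)
      }
    }
  }
  check_side(rx$substrates, "substrate", "sub_carbon", "substrate")
  check_side(rx$products, "product", "prod_carbon", "product")
  invisible(TRUE)
}

# breadth-first reachability over reactions (a reaction can fire once any of
# its carbon-bearing substrates is reachable; co-substrates such as the
# acetyl donor are assumed available from the pool)
check_reachability <- function(model) {
  for (s in model$substrates) {
    reach <- s
    repeat {
      new <- reach
      for (rx in model$reactions) {
        if (any(rx$substrates$name %in% reach)) {
          new <- union(new, rx$products$name)
        }
      }
      if (length(new) == length(reach)) break
      reach <- new
    }
    if (!model$terminal_product %in% reach) {
      stop("terminal product '", model$terminal_product,
           "' is not reachable from substrate '", s, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("<pathway_model>", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  for (b in names(x$branch_index)) {
    cat("  ", b, ": ", length(x$branch_index[[b]]), " reactions (",
        paste(x$branch_index[[b]], collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pathway_model <- function(x, ...) {
  purrr::map_dfr(x$reactions, function(rx) {
    fmt <- function(tb) paste(
      ifelse(tb$coef == 1, tb$name, paste(tb$coef, tb$name)),
      collapse = " + ")
    tibble::tibble(id = rx$id, branch = rx$branch, enzyme = rx$enzyme,
                   equation = paste(fmt(rx$substrates), "->",
                                    fmt(rx$products)))
  })
}

#' Metabolite formula lookup table
#'
#' Returns the metabolite table (name, formula, carbon count) of the packaged
#' pathway definition, used as the default lookup for [balance_equation()]
#' and [carbon_recovery()].
#'
#' @return Tibble with columns `name`, `formula`, `n_carbons`.
#' @examples
#' default_metabolites()
#' @export
default_metabolites <- function() {
  env <- pkg_cache()
  if (is.null(env$metabolites)) {
    env$metabolites <- load_pathway()$metabolites
  }
  env$metabolites
}

pkg_cache <- local({
  env <- new.env(parent = emptyenv())
  function() env
})

`%||%` <- function(x, y) if (is.null(x)) y else x
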