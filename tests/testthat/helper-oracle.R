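# Independent Monte-Carlo oracle for the steady-state tracer model, written
# directly from the pathway chemistry for a lysine substrate (it shares no
# code with propagate_labels):
#  - a butyrate molecule comes from the lysine branch with probability theta
#    (carbons = lysine C3..C6) or from condensation of two acetyl units
#    (unit A -> C1,C2; unit B -> C3,C4);
#  - an acetyl unit is drawn from the source mixture; the "recycled" source
#    returns, with probability theta, one of the two thiolytic halves of a
#    lysine-branch butyryl molecule (lysine C3,C4 or C5,C6 with the methyl at
#    acetyl C2), and otherwise an acetyl unit drawn afresh from the pool.
#
# Returns the empirical 16-state butyrate distribution (named by the
# carbon-1-first pattern string) and the 4-state acetate distribution.
mc_trace_lysine <- function(label_positions, theta, weights, n = 1e5,
                            exo_pattern = c(0L, 0L), seed = 1) {
  p <- integer(6)
  p[label_positions] <- 1L
  halves <- list(p[3:4], p[5:6])
  terminal <- list(
    lysine_c1c2 = p[1:2],
    exogenous_acetate = as.integer(exo_pattern),
    glycolysis = c(0L, 0L)
  )
  w <- weights / sum(weights)

  set.seed(seed)
  sample_acetyl <- function(n_units) {
    out <- matrix(NA_integer_, n_units, 2)
    todo <- seq_len(n_units)
    while (length(todo)) {
      src <- sample(names(w), length(todo), replace = TRUE, prob = w)
      is_rec <- src == "recycled"
      res <- todo[!is_rec]
      if (length(res)) {
        patt <- terminal[src[!is_rec]]
        out[res, ] <- do.call(rbind, patt)
      }
      rec <- todo[is_rec]
      if (length(rec)) {
        from_lys <- stats::runif(length(rec)) < theta
        done <- rec[from_lys]
        if (length(done)) {
          pick <- sample(1:2, length(done), replace = TRUE)
          out[done, ] <- do.call(rbind, halves[pick])
        }
        todo <- rec[!from_lys]
      } else {
        todo <- integer()
      }
    }
    out
  }

  units <- sample_acetyl(2 * n)
  from_lys <- stats::runif(n) < theta
  but <- matrix(NA_integer_, n, 4)
  if (any(from_lys)) {
    but[from_lys, ] <- matrix(rep(p[3:6], sum(from_lys)), ncol = 4,
                              byrow = TRUE)
  }
  idx <- which(!from_lys)
  if (length(idx)) {
    but[idx, ] <- cbind(units[idx, , drop = FALSE],
                        units[n + idx, , drop = FALSE])
  }
  pat4 <- apply(but, 1, paste, collapse = "")
  lv4 <- apply(expand_patterns(4), 1, paste, collapse = "")
  acetate_units <- sample_acetyl(n)
  pat2 <- apply(acetate_units, 1, paste, collapse = "")
  lv2 <- apply(expand_patterns(2), 1, paste, collapse = "")
  list(
    butyrate = table(factor(pat4, levels = lv4)) / n,
    acetate = table(factor(pat2, levels = lv2)) / n,
    n = n
  )
}

# all 2^n patterns in the same (carbon 1 = least significant bit) order the
# package uses for its distribution names
expand_patterns <- function(n) {
  states <- 0:(2^n - 1)
  m <- vapply(seq_len(n),
              function(j) as.integer(bitwAnd(states, 2^(j - 1)) > 0),
              integer(length(states)))
  matrix(m, nrow = length(states))
}

# expected number of 13C atoms per molecule under a distribution named by
# pattern strings
expected_labels <- function(dist) {
  bits <- vapply(names(dist),
                 function(s) sum(as.integer(strsplit(s, "")[[1]])),
                 numeric(1))
  sum(bits * dist)
}

ref_lysine_equation <- function() {
  balance_equation(c("lysine", "water"),
                   c("butyrate", "acetate", "ammonia"))
}
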