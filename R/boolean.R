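#' Partial Boolean truth tables
#'
#' A `boolean_table` lists a subset of the rows of a Boolean function of
#' `n` inputs: each row is an input pattern (a bit-string, read left to right
#' as inputs `1..n`) and its required output. Unlisted patterns are
#' unconstrained. Duplicated consistent rows are collapsed; conflicting
#' duplicates are an error.
#'
#' @param patterns Character vector of bit-strings (all the same length), or
#'   a 0/1 matrix with one row per pattern.
#' @param outputs Integer vector of 0/1 outputs, one per pattern.
#'
#' @return A tibble of class `boolean_table` with columns `pattern` and
#'   `output` and attribute `n_inputs`.
#' @seealso [make_cfbp()], [make_xor()], [is_linearly_separable()]
#' @export
#' @examples
#' boolean_table(c("00", "01", "10", "11"), c(0, 0, 0, 1))  # AND
boolean_table <- function(patterns, outputs) {
  if (is.matrix(patterns)) {
    patterns <- apply(patterns, 1, paste, collapse = "")
  }
  stopifnot(is.character(patterns), length(patterns) == length(outputs))
  outputs <- as.integer(outputs)
  if (length(patterns) == 0) {
    abort("a boolean_table needs at least one row",
          class = "satif_error_invalid_table")
  }
  if (!all(outputs %in% c(0L, 1L))) {
    abort("outputs must be 0 or 1", class = "satif_error_invalid_table")
  }
  n <- nchar(patterns[1])
  if (any(nchar(patterns) != n) || any(!grepl("^[01]+$", patterns))) {
    abort("patterns must be 0/1 bit-strings of equal length",
          class = "satif_error_invalid_table")
  }
  tbl <- tibble::tibble(pattern = patterns, output = outputs) |>
    dplyr::distinct()
  if (anyDuplicated(tbl$pattern)) {
    abort("duplicated pattern with conflicting outputs",
          class = "satif_error_invalid_table")
  }
  structure(tbl, n_inputs = n, class = c("boolean_table", class(tbl)))
}

#' Number of inputs of a truth table
#' @param table A `boolean_table`.
#' @return Integer.
#' @export
n_inputs <- function(table) attr(table, "n_inputs")

# rows-by-inputs 0/1 matrix of the table's patterns
pattern_matrix <- function(table) {
  do.call(rbind, lapply(table$pattern,
                        function(p) as.integer(strsplit(p, "")[[1]])))
}

#' The compact feature binding problem family
#'
#' Builds the partial truth table of the compact feature binding problem
#' (cFBP) over `2m` inputs split into clusters `A = {1..m}` and
#' `B = {m+1..2m}`. Activating one whole cluster ("clustered" rows: the
#' indicator of B, then of A) must give output 0, while the two "scattered"
#' m-tuples `S2` and `S1` — complements of one another, each straddling both
#' clusters — must give output 1. Because the two 0-rows and the two 1-rows
#' partition the same input set, summing the corresponding threshold
#' inequalities yields contradictory bounds on twice the threshold: no
#' weight vector can realise the table, for any `m >= 2` (see
#' [check_pairing_contradiction()]).
#'
#' For `m = 2` the rows are `0011 -> 0`, `1100 -> 0`, `0101 -> 1`,
#' `1010 -> 1`: a four-input task as hard as XOR yet solvable with purely
#' excitatory inputs.
#'
#' @param m Cluster size, >= 2; the table has `2m` inputs and 4 rows.
#' @return A [boolean_table()].
#' @export
#' @examples
#' make_cfbp(2)
#' make_cfbp(3)
make_cfbp <- function(m = 2) {
  if (!is.numeric(m) || m < 2 || m != round(m)) {
    abort("m must be an integer >= 2", class = "satif_error_domain")
  }
  m <- as.integer(m)
  n <- 2L * m
  ind <- function(idx) {
    p <- integer(n); p[idx] <- 1L; paste(p, collapse = "")
  }
  A <- seq_len(m)
  B <- m + seq_len(m)
  s1 <- c(seq_len(ceiling(m / 2)), m + seq_len(floor(m / 2)))
  s2 <- setdiff(c(A, B), s1)
  boolean_table(c(ind(B), ind(A), ind(s2), ind(s1)), c(0L, 0L, 1L, 1L))
}

#' The full two-input XOR table
#'
#' @return A [boolean_table()] with the four rows of exclusive-or — the
#'   textbook linearly non-separable function.
#' @export
#' @examples
#' is_linearly_separable(make_xor())
make_xor <- function() {
  boolean_table(c("00", "01", "10", "11"), c(0L, 1L, 1L, 0L))
}

#' Certify linear separability of a partial Boolean function
#'
#' Decides whether weights `w` and a threshold `Theta` exist with
#' `w . X >= Theta` exactly on the output-1 rows. Two independent routes:
#'
#' * `method = "lp"`: linear-programming feasibility of
#'   `{w.X >= Theta (1-rows); w.X <= Theta - 1 (0-rows)}`. The unit margin
#'   loses no generality because the strict system is scale-invariant.
#'   Solved with [boot::simplex()] after splitting the free variables into
#'   non-negative parts.
#' * `method = "exhaustive"`: brute-force search over integer weights in
#'   `{-8..8}^n` and thresholds in `{-32..32}`; only for `n <= 4` but
#'   independent of the LP, so the two can cross-check each other.
#'
#' A returned witness is replayed through the defining inequality on every
#' row before being accepted.
#'
#' @param table A [boolean_table()].
#' @param method `"lp"` (any `n`) or `"exhaustive"` (`n <= 4`).
#' @return An object of class `separability_certificate`: list with
#'   `separable`, `weights`, `theta` (witness, `NULL` when non-separable),
#'   `method`, `n_inputs`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' is_linearly_separable(make_cfbp(2))          # non-separable
#' is_linearly_separable(boolean_table(c("00", "01", "10", "11"),
#'                                     c(0, 0, 0, 1)))  # AND: w=(1,1), 2
is_linearly_separable <- function(table, method = c("lp", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "boolean_table"))
  n <- n_inputs(table)
  X <- pattern_matrix(table)
  y <- table$output
  res <- if (method == "lp") separable_lp(X, y) else {
    if (n > 4) {
      abort("exhaustive search supports at most 4 inputs",
            class = "satif_error_capability")
    }
    separable_exhaustive(X, y)
  }
  if (res$separable &&
      !witness_valid(res$weights, res$theta, X, y)) {
    abort("internal error: witness failed replay", class = "satif_error_state")
  }
  structure(
    list(separable = res$separable, weights = res$weights, theta = res$theta,
         method = method, n_inputs = n, table = table),
    class = "separability_certificate"
  )
}

# exact replay of the definition: w.X >= theta iff output 1
witness_valid <- function(w, theta, X, y, eps = 1e-7) {
  s <- as.numeric(X %*% w)
  all((s >= theta - eps) == (y == 1))
}

separable_lp <- function(X, y) {
  n <- ncol(X)
  nv <- 2 * n + 2  # w+, w-, theta+, theta-
  rows <- lapply(seq_len(nrow(X)), function(i) {
    r <- c(X[i, ], -X[i, ], -1, 1)  # coefficients of w.x - theta
    if (y[i] == 1) list(a = r, b = 0) else list(a = -r, b = 1)
  })
  A2 <- do.call(rbind, lapply(rows, `[[`, "a"))
  b2 <- vapply(rows, `[[`, numeric(1), "b")
  # minimise total mass under a generous bound; feasibility is what matters
  res <- boot::simplex(a = rep(1, nv), A1 = matrix(1, 1, nv), b1 = 1e4,
                       A2 = A2, b2 = b2, maxi = FALSE)
  if (res$solved != 1) {
    return(list(separable = FALSE, weights = NULL, theta = NULL))
  }
  z <- as.numeric(res$soln)
  list(separable = TRUE,
       weights = z[seq_len(n)] - z[n + seq_len(n)],
       theta = z[2 * n + 1] - z[2 * n + 2])
}

separable_exhaustive <- function(X, y, w_bound = 8L, theta_bound = 32L) {
  n <- ncol(X)
  if (all(y == 1)) return(list(separable = TRUE, weights = rep(0, n), theta = 0))
  if (all(y == 0)) return(list(separable = TRUE, weights = rep(0, n), theta = 1))
  W <- as.matrix(expand.grid(rep(list(seq(-w_bound, w_bound)), n)))
  S <- W %*% t(X)  # candidate weights x rows
  s1 <- S[, y == 1, drop = FALSE]
  s0 <- S[, y == 0, drop = FALSE]
  min1 <- do.call(pmin, as.data.frame(s1))
  max0 <- do.call(pmax, as.data.frame(s0))
  ok <- which(max0 < min1 & abs(min1) <= theta_bound)
  if (length(ok) == 0) {
    return(list(separable = FALSE, weights = NULL, theta = NULL))
  }
  i <- ok[1]
  list(separable = TRUE, weights = as.numeric(W[i, ]), theta = min1[i])
}

#' Pairing certificate of non-separability
#'
#' Searches the table for two disjoint output-0 rows and two disjoint
#' output-1 rows whose active-input multiset unions coincide. When such a
#' quadruple exists, summing the 0-row inequalities bounds the total weight
#' of the shared union by `2*Theta` from above while the 1-row inequalities
#' bound it strictly from below — a contradiction, so the table is certified
#' linearly non-separable without any search over weights. This is a
#' sufficient (not necessary) certificate over rows with at least one active
#' input (the all-zero pattern is not a "tuple" and is excluded); XOR is
#' therefore not covered by it and is handled by the generic checker.
#'
#' @param table A [boolean_table()].
#' @return `TRUE` or `FALSE`; when `TRUE`, the certifying rows are attached
#'   as attribute `"pairing"` (a tibble with columns `role` and `pattern`).
#' @export
#' @examples
#' check_pairing_contradiction(make_cfbp(2))  # TRUE: (1,2),(3,4) vs (1,3),(2,4)
check_pairing_contradiction <- function(table) {
  stopifnot(inherits(table, "boolean_table"))
  X <- pattern_matrix(table)
  active <- rowSums(X) > 0
  i0 <- which(table$output == 0 & active)
  i1 <- which(table$output == 1 & active)
  disjoint_pairs <- function(idx) {
    if (length(idx) < 2) return(list())
    cmb <- utils::combn(idx, 2, simplify = FALSE)
    Filter(function(p) all(X[p[1], ] + X[p[2], ] <= 1), cmb)
  }
  for (p0 in disjoint_pairs(i0)) {
    u0 <- X[p0[1], ] + X[p0[2], ]
    for (p1 in disjoint_pairs(i1)) {
      if (all(u0 == X[p1[1], ] + X[p1[2], ])) {
        pairing <- tibble::tibble(
          role = c("zero", "zero", "one", "one"),
          pattern = table$pattern[c(p0, p1)])
        return(structure(TRUE, pairing = pairing))
      }
    }
  }
  FALSE
}

#' @export
print.separability_certificate <- function(x, ...) {
  if (x$separable) {
    cat(sprintf("<separability_certificate: SEPARABLE (%s method)>\n  w = (%s), Theta = %g\n",
                x$method, paste(format(x$weights, digits = 4), collapse = ", "),
                x$theta))
  } else {
    cat(sprintf("<separability_certificate: NON-SEPARABLE (%s method)>\n", x$method))
  }
  invisible(x)
}

#' Tidy a separability certificate into per-input weights
#' @param x A `separability_certificate`.
#' @param ... Unused.
#' @return A tibble with one row per input (`term`, `weight`); zero rows when
#'   non-separable.
#' @export
tidy.separability_certificate <- function(x, ...) {
  if (!x$separable) {
    return(tibble::tibble(term = character(), weight = double()))
  }
  tibble::tibble(term = paste0("x", seq_len(x$n_inputs)), weight = x$weights)
}

#' One-row summary of a separability certificate
#' @param x A `separability_certificate`.
#' @param ... Unused.
#' @return A one-row tibble: verdict, method, threshold, input and row counts.
#' @export
glance.separability_certificate <- function(x, ...) {
  tibble::tibble(separable = x$separable, method = x$method,
                 theta = if (x$separable) x$theta else NA_real_,
                 n_inputs = x$n_inputs, n_rows = nrow(x$table))
}
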