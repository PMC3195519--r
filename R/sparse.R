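#' Compressed sparse row (CSR) system matrix
#'
#' The solver operates on symmetric sparse FEM matrices stored in
#' compressed sparse row format: a vector of row offsets, sorted column
#' indices, and the nonzero values, together with a precision tag. Values
#' are always held in an R double (or complex) vector; a matrix tagged
#' `"single"` has every value rounded to the nearest IEEE single-precision
#' number and is processed by single-precision arithmetic kernels.
#'
#' @param row_ptr integer vector of length `n + 1`, 0-based offsets into
#'   `col_ind`/`values`.
#' @param col_ind integer vector of 0-based column indices, sorted and
#'   unique within each row.
#' @param values numeric or complex vector of nonzero values, same length
#'   as `col_ind`.
#' @param n matrix dimension (the systems are square).
#' @param precision `"double"` or `"single"`.
#' @return An object of class `sparse_system`.
#' @export
sparse_system <- function(row_ptr, col_ind, values, n,
                          precision = "double") {
  row_ptr <- as.integer(row_ptr)
  col_ind <- as.integer(col_ind)
  stopifnot(length(row_ptr) == n + 1L,
            row_ptr[1L] == 0L,
            row_ptr[n + 1L] == length(col_ind),
            length(values) == length(col_ind))
  precision <- match.arg(precision, c("double", "single"))
  structure(list(n = as.integer(n), row_ptr = row_ptr, col_ind = col_ind,
                 values = values, precision = precision),
            class = "sparse_system")
}

#' Convert a dense matrix to a `sparse_system`
#'
#' Intended for small test systems and oracles; zero entries are dropped.
#'
#' @param m a square numeric or complex matrix.
#' @param precision precision tag of the result.
#' @return A [sparse_system()].
#' @export
as_sparse_system <- function(m, precision = "double") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  keep <- which(m != 0, arr.ind = TRUE)
  ord <- order(keep[, 1L], keep[, 2L])
  keep <- keep[ord, , drop = FALSE]
  vals <- m[keep]
  counts <- tabulate(keep[, 1L], nbins = n)
  sparse_system(row_ptr = c(0L, cumsum(counts)),
                col_ind = keep[, 2L] - 1L,
                values = vals, n = n, precision = precision)
}

#' @export
as.matrix.sparse_system <- function(x, ...) {
  m <- matrix(if (is.complex(x$values)) 0 + 0i else 0, x$n, x$n)
  rows <- rep.int(seq_len(x$n), diff(x$row_ptr))
  m[cbind(rows, x$col_ind + 1L)] <- x$values
  m
}

#' @export
print.sparse_system <- function(x, ...) {
  kind <- if (is.complex(x$values)) "complex" else "real"
  cat(sprintf("<sparse_system %d x %d, %d nonzeros, %s, %s precision>\n",
              x$n, x$n, length(x$values), kind, x$precision))
  invisible(x)
}

#' Sparse matrix-vector product
#'
#' Dispatches on the value kind and precision tag of the system: real
#' double, real single (all products and accumulations performed in IEEE
#' single precision), or complex double.
#'
#' @param S a [sparse_system()].
#' @param x vector of length `S$n`.
#' @return The product `S %*% x` as a plain vector.
#' @export
sp_matvec <- function(S, x) {
  stopifnot(length(x) == S$n)
  if (is.complex(S$values) || is.complex(x)) {
    csr_matvec_cplx(S$row_ptr, S$col_ind, as.complex(S$values),
                    as.complex(x))
  } else if (S$precision == "single") {
    csr_matvec_sgl(S$row_ptr, S$col_ind, S$values, x)
  } else {
    csr_matvec_dbl(S$row_ptr, S$col_ind, S$values, x)
  }
}

#' Diagonal of a sparse system
#'
#' @param S a [sparse_system()].
#' @return Vector of diagonal entries (zeros where the diagonal is not
#'   stored).
#' @export
sp_diag <- function(S) {
  d <- if (is.complex(S$values)) complex(S$n) else numeric(S$n)
  rows <- rep.int(seq_len(S$n), diff(S$row_ptr))
  hit <- S$col_ind + 1L == rows
  d[rows[hit]] <- S$values[hit]
  d
}

same_pattern <- function(a, b) {
  a$n == b$n && identical(a$row_ptr, b$row_ptr) &&
    identical(a$col_ind, b$col_ind)
}

# Value-wise linear combination of systems sharing one sparsity pattern.
sp_combine <- function(systems, coefs) {
  stopifnot(length(systems) == length(coefs), length(systems) >= 1L)
  base <- systems[[1L]]
  vals <- coefs[[1L]] * base$values
  for (k in seq_along(systems)[-1L]) {
    if (!same_pattern(base, systems[[k]]))
      stop("sparse systems do not share a sparsity pattern")
    vals <- vals + coefs[[k]] * systems[[k]]$values
  }
  sparse_system(base$row_ptr, base$col_ind, vals, base$n, "double")
}

#' Demote a sparse system to single precision
#'
#' Rounds every stored value to the nearest IEEE single-precision number
#' (half-ulp rounding) while keeping the sparsity pattern; the precision
#' tag becomes `"single"` so subsequent mat-vec products run in
#' single-precision arithmetic. The production path for single-precision
#' solves is always assemble-in-double-then-demote: accumulating element
#' contributions natively in single precision loses accuracy when summands
#' of very different magnitude meet at high-valence vertices.
#'
#' @param S a double-precision real [sparse_system()].
#' @return The demoted system.
#' @export
demote_precision <- function(S) {
  stopifnot(inherits(S, "sparse_system"))
  if (is.complex(S$values))
    stop("demotion is defined for real-valued systems; expand complex ",
         "systems to real block form first")
  if (S$precision == "single") return(S)
  sparse_system(S$row_ptr, S$col_ind, round_to_single(S$values), S$n,
                "single")
}

#' Round a numeric vector to single precision
#'
#' Each entry is replaced by the nearest representable IEEE single value
#' (stored in a double vector). Errors if a finite value overflows the
#' single-precision range.
#'
#' @param x numeric vector.
#' @return Rounded vector.
#' @export
to_single <- function(x) round_to_single(as.numeric(x))
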