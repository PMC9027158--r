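#' Primitive roots of an odd prime modulus
#'
#' A base \code{a} is a primitive root modulo the prime \code{p} when its
#' powers \code{a^1, ..., a^(p-1) (mod p)} enumerate every nonzero residue,
#' i.e. when \code{a} generates the full multiplicative group.  The test is
#' explicit power enumeration: \code{p} is small by design here, so no
#' factorization shortcuts are needed.
#'
#' @param p an odd prime modulus, \code{p >= 3}.
#' @return integer vector of all primitive roots of \code{p}, ascending.
#' @examples
#' find_primitive_roots(17)  # 3 5 6 7 10 11 12 14
#' @export
find_primitive_roots <- function(p) {
  check_prime_modulus(p)
  p <- as.integer(p)
  roots <- integer(0)
  for (a in 2:(p - 1L)) {
    if (length(unique(power_cycle(a, p))) == p - 1L) {
      roots <- c(roots, a)
    }
  }
  roots
}

#' Cyclic group table for a prime modulus
#'
#' One row per primitive root \code{a} (ascending), with entry \code{i}
#' equal to \code{a^i mod p} for \code{i = 1, ..., p-1}.  Each row is a
#' permutation of \code{1..p-1} and ends in 1 (Fermat's little theorem).
#' For \code{p = 17} this yields the eight length-16 generator sequences
#' that define the CGP17Pat comparison patterns.
#'
#' @param p an odd prime modulus, \code{p >= 3}.  Restricted to
#'   \code{(p-1)/2 <= 16} so pattern codes fit 16-bit histograms.
#' @return an object of class \code{cgp_group_table}: an integer matrix with
#'   \code{H} rows (one per primitive root) and \code{p-1} columns, with
#'   attributes \code{p} and \code{bases}.
#' @examples
#' generate_group_table(17)
#' @export
generate_group_table <- function(p) {
  check_prime_modulus(p)
  p <- as.integer(p)
  if ((p - 1L) / 2L > 16L) {
    stop("modulus too large: (p-1)/2 must be <= 16 so codes fit histograms",
         call. = FALSE)
  }
  bases <- find_primitive_roots(p)
  tab <- t(vapply(bases, power_cycle, integer(p - 1L), p = p))
  structure(tab, p = p, bases = bases, class = "cgp_group_table")
}

#' Center-symmetric comparison pairs from a group table
#'
#' For every group row \code{G_h} the pattern pairs the \code{k}-th and
#' \code{(p-k)}-th entries, \code{k = 1..(p-1)/2}.  Each pair gives one
#' sign-comparison bit of the pattern code; across the pairs of one group
#' every window position \code{1..p-1} is used exactly once, and the pair
#' products satisfy \code{G_h(k) * G_h(p-k) = a_h (mod p)}.
#'
#' @param table a \code{cgp_group_table} from [generate_group_table()].
#' @return an object of class \code{cgp_pattern_set}: a list with
#'   \code{left} and \code{right} integer matrices (\code{H} rows,
#'   \code{bit_width} columns; bit \code{k} compares window position
#'   \code{left[h, k]} against \code{right[h, k]}), \code{bit_width}
#'   \code{= (p-1)/2}, \code{p} and \code{bases}.
#' @export
build_pattern_pairs <- function(table) {
  if (!inherits(table, "cgp_group_table")) {
    stop("`table` must be a cgp_group_table", call. = FALSE)
  }
  p <- attr(table, "p")
  half <- (p - 1L) %/% 2L
  left <- unclass(table)[, seq_len(half), drop = FALSE]
  right <- unclass(table)[, p - seq_len(half), drop = FALSE]
  attributes(left) <- attributes(right) <- list(dim = dim(left))
  structure(
    list(left = left, right = right, bit_width = half,
         p = p, bases = attr(table, "bases")),
    class = "cgp_pattern_set"
  )
}

#' @export
print.cgp_group_table <- function(x, ...) {
  cat("Cyclic group table, modulus p =", attr(x, "p"), "\n")
  cat(nrow(x), "generator(s):", paste(attr(x, "bases"), collapse = ", "), "\n")
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m),
                        dimnames = list(paste0("G", seq_len(nrow(m))),
                                        seq_len(ncol(m))))
  print(m)
  invisible(x)
}

#' @export
print.cgp_pattern_set <- function(x, ...) {
  cat("Center-symmetric pattern set: ", nrow(x$left), " pattern(s), ",
      x$bit_width, " bit(s) each (p = ", x$p, ")\n", sep = "")
  invisible(x)
}

# a^1..a^(p-1) mod p by repeated multiplication (values stay < p^2,
# exact in double precision for the small moduli supported here)
power_cycle <- function(a, p) {
  out <- integer(p - 1L)
  v <- 1
  for (i in seq_len(p - 1L)) {
    v <- (v * a) %% p
    out[i] <- as.integer(v)
  }
  out
}

check_prime_modulus <- function(p) {
  if (length(p) != 1L || !is.numeric(p) || is.na(p) || p != floor(p)) {
    stop("modulus p must be a single integer", call. = FALSE)
  }
  if (p < 3 || !is_prime(p)) {
    stop("modulus p must be an odd prime >= 3", call. = FALSE)
  }
  invisible(TRUE)
}

is_prime <- function(n) {
  n <- as.integer(n)
  if (n < 2L) return(FALSE)
  if (n < 4L) return(TRUE)
  if (n %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= n) {
    if (n %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}
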