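# Sparse multivariate polynomials and rational functions in the laziness
# parameters. Coefficients are doubles; on the graphs where symbolic chains
# are built (cycles, degree 2) every kernel coefficient is dyadic, so
# arithmetic is exact. Rational functions are kept unreduced and compared by
# cross-multiplication, avoiding any need for multivariate GCDs.

#' Polynomial in named variables
#'
#' Constructs a sparse multivariate polynomial. These objects support `+`,
#' `-`, `*` and `^` (integer powers) among themselves and with numerics, and
#' are the coefficient ring used by [build_chain()] when `symbolic = TRUE`.
#'
#' @param x a variable name (single string) for [poly_var()], or a single
#'   numeric for [poly_const()].
#' @return an object of class `lrw_poly`.
#' @examples
#' p <- poly_var("p")
#' (1 - p) * (1 + p) + p^2   # constant 1
#' @export
poly_var <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  new_poly(vars = x, expo = matrix(1L, 1L, 1L), coef = 1)
}

#' @rdname poly_var
#' @export
poly_const <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L)
  new_poly(vars = character(0), expo = matrix(0L, 1L, 0L), coef = as.numeric(x))
}

new_poly <- function(vars, expo, coef) {
  poly_norm(structure(list(vars = vars, expo = expo, coef = coef),
                      class = "lrw_poly"))
}

is_poly <- function(x) inherits(x, "lrw_poly")

as_poly <- function(x) {
  if (is_poly(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(poly_const(x))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to a polynomial")
}

# canonical form: drop ~0 terms, merge duplicates, drop unused variables,
# order variables alphabetically and terms lexicographically by exponents
poly_norm <- function(p, tol = 1e-12) {
  vars <- p$vars; expo <- p$expo; coef <- p$coef
  if (length(vars)) {
    ord <- order(vars)
    vars <- vars[ord]
    expo <- expo[, ord, drop = FALSE]
  }
  if (length(coef)) {
    key <- apply(expo, 1L, paste, collapse = ",")
    agg <- tapply(coef, key, sum)
    expo <- expo[match(names(agg), key), , drop = FALSE]
    coef <- as.numeric(agg)
    keep <- abs(coef) > tol
    coef <- coef[keep]; expo <- expo[keep, , drop = FALSE]
  }
  if (length(vars)) {
    used <- colSums(abs(expo)) > 0
    vars <- vars[used]
    expo <- expo[, used, drop = FALSE]
  }
  if (length(coef) && ncol(expo)) {
    ord <- do.call(order, as.data.frame(expo))
    expo <- expo[ord, , drop = FALSE]
    coef <- coef[ord]
  }
  structure(list(vars = vars, expo = expo, coef = coef), class = "lrw_poly")
}

poly_is_zero <- function(p) length(p$coef) == 0L

# bring two polynomials onto a common variable set
poly_align <- function(a, b) {
  vars <- sort(union(a$vars, b$vars))
  expand <- function(p) {
    e <- matrix(0L, nrow(p$expo), length(vars))
    if (length(p$vars)) e[, match(p$vars, vars)] <- p$expo
    list(vars = vars, expo = e, coef = p$coef)
  }
  list(a = expand(a), b = expand(b), vars = vars)
}

poly_add <- function(a, b) {
  al <- poly_align(as_poly(a), as_poly(b))
  new_poly(al$vars, rbind(al$a$expo, al$b$expo), c(al$a$coef, al$b$coef))
}

poly_mul <- function(a, b) {
  a <- as_poly(a); b <- as_poly(b)
  if (poly_is_zero(a) || poly_is_zero(b)) return(poly_const(0))
  al <- poly_align(a, b)
  na <- length(al$a$coef); nb <- length(al$b$coef)
  ia <- rep(seq_len(na), times = nb); ib <- rep(seq_len(nb), each = na)
  new_poly(al$vars, al$a$expo[ia, , drop = FALSE] + al$b$expo[ib, , drop = FALSE],
           al$a$coef[ia] * al$b$coef[ib])
}

poly_neg <- function(p) { p <- as_poly(p); p$coef <- -p$coef; p }

poly_pow <- function(p, k) {
  stopifnot(k >= 0, k == round(k))
  out <- poly_const(1)
  for (i in seq_len(k)) out <- poly_mul(out, p)
  out
}

#' @export
Ops.lrw_poly <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*", "^")) {
    if (missing(e2)) { # unary
      return(switch(.Generic, "+" = e1, "-" = poly_neg(e1),
                    stop("unsupported unary operator for polynomials")))
    }
    switch(.Generic,
           "+" = poly_add(e1, e2),
           "-" = poly_add(e1, poly_neg(e2)),
           "*" = poly_mul(e1, e2),
           "^" = poly_pow(e1, e2))
  } else if (.Generic == "==") {
    poly_equal(e1, e2)
  } else {
    stop("operator '", .Generic, "' is not defined for polynomials; ",
         "use rational-function helpers for division")
  }
}

#' Evaluate a polynomial
#'
#' @param p an `lrw_poly`.
#' @param vals named numeric vector supplying every variable of `p`.
#' @return a numeric scalar.
#' @export
poly_eval <- function(p, vals = numeric(0)) {
  p <- as_poly(p)
  if (poly_is_zero(p)) return(0)
  if (length(p$vars)) {
    missing_vars <- setdiff(p$vars, names(vals))
    if (length(missing_vars))
      stop("no value supplied for variable(s): ",
           paste(missing_vars, collapse = ", "))
    v <- vals[p$vars]
    sum(p$coef * apply(p$expo, 1L, function(e) prod(v^e)))
  } else {
    sum(p$coef)
  }
}

#' @rdname poly_eval
#' @param var variable name to differentiate with respect to.
#' @export
poly_deriv <- function(p, var) {
  p <- as_poly(p)
  j <- match(var, p$vars)
  if (is.na(j)) return(poly_const(0))
  e <- p$expo[, j]
  keep <- e > 0
  if (!any(keep)) return(poly_const(0))
  expo <- p$expo[keep, , drop = FALSE]
  coef <- p$coef[keep] * expo[, j]
  expo[, j] <- expo[, j] - 1L
  new_poly(p$vars, expo, coef)
}

# substitute a numeric value for one variable, returning a polynomial in
# the remaining variables
poly_subst <- function(p, var, value) {
  p <- as_poly(p)
  j <- match(var, p$vars)
  if (is.na(j)) return(p)
  coef <- p$coef * value^p$expo[, j]
  new_poly(p$vars, `[<-`(p$expo, , j, 0L), coef)
}

rat_subst <- function(r, var, value) {
  r <- as_rat(r)
  new_rat(poly_subst(r$num, var, value), poly_subst(r$den, var, value))
}

poly_total_degree <- function(p) {
  if (poly_is_zero(p) || !length(p$vars)) return(0L)
  max(rowSums(p$expo))
}

#' Compare two polynomials coefficient-by-coefficient
#'
#' Both are brought to canonical form; equality means identical monomials
#' with coefficients agreeing within `tol` (relative to the largest
#' coefficient).
#'
#' @param a,b polynomials (or numerics).
#' @param tol absolute/relative coefficient tolerance.
#' @return logical.
#' @export
poly_equal <- function(a, b, tol = 1e-9) {
  d <- poly_add(a, poly_neg(b))
  if (poly_is_zero(d)) return(TRUE)
  scale <- max(1, abs(c(as_poly(a)$coef, as_poly(b)$coef, 0)))
  all(abs(d$coef) <= tol * scale)
}

# drop trailing (leading-degree) coefficients that are numerically zero, so
# polyroot() sees the true degree
trim_poly_coefs <- function(coefs, tol = 1e-9) {
  scale <- max(abs(coefs), 1e-300)
  while (length(coefs) > 1L && abs(coefs[length(coefs)]) < tol * scale)
    coefs <- coefs[-length(coefs)]
  coefs
}

# ascending coefficient vector of a univariate polynomial, for polyroot()
poly_coefs_univariate <- function(p, var) {
  p <- as_poly(p)
  extra <- setdiff(p$vars, var)
  if (length(extra))
    stop("polynomial is not univariate in '", var, "': also involves ",
         paste(extra, collapse = ", "))
  if (poly_is_zero(p)) return(0)
  deg <- if (length(p$vars)) max(p$expo[, 1L]) else 0L
  coefs <- numeric(deg + 1L)
  if (length(p$vars)) {
    coefs[p$expo[, 1L] + 1L] <- p$coef
  } else {
    coefs[1L] <- sum(p$coef)
  }
  coefs
}

#' @export
format.lrw_poly <- function(x, digits = 6, ...) {
  if (poly_is_zero(x)) return("0")
  terms <- vapply(seq_along(x$coef), function(i) {
    mono <- ""
    if (length(x$vars)) {
      e <- x$expo[i, ]
      parts <- x$vars[e > 0]
      pows <- e[e > 0]
      mono <- paste(ifelse(pows == 1L, parts, paste0(parts, "^", pows)),
                    collapse = "*")
    }
    cf <- x$coef[i]
    if (nzchar(mono)) {
      if (cf == 1) mono
      else if (cf == -1) paste0("-", mono)
      else paste0(format(cf, digits = digits), "*", mono)
    } else {
      format(cf, digits = digits)
    }
  }, character(1))
  out <- paste(terms, collapse = " + ")
  gsub("\\+ -", "- ", out)
}

#' @export
print.lrw_poly <- function(x, ...) {
  cat("<polynomial> ", format(x), "\n", sep = "")
  invisible(x)
}

## ---- rational functions -------------------------------------------------

new_rat <- function(num, den = poly_const(1)) {
  num <- as_poly(num); den <- as_poly(den)
  if (poly_is_zero(den)) stop("rational function with zero denominator")
  structure(list(num = num, den = den), class = "lrw_rat")
}

is_rat <- function(x) inherits(x, "lrw_rat")

as_rat <- function(x) {
  if (is_rat(x)) return(x)
  new_rat(as_poly(x))
}

rat_add <- function(a, b) {
  a <- as_rat(a); b <- as_rat(b)
  if (poly_equal(a$den, b$den, tol = 0))
    return(new_rat(poly_add(a$num, b$num), a$den))
  new_rat(poly_add(poly_mul(a$num, b$den), poly_mul(b$num, a$den)),
          poly_mul(a$den, b$den))
}

rat_sub <- function(a, b) rat_add(a, rat_neg(b))
rat_neg <- function(a) { a <- as_rat(a); a$num <- poly_neg(a$num); a }

rat_mul <- function(a, b) {
  a <- as_rat(a); b <- as_rat(b)
  new_rat(poly_mul(a$num, b$num), poly_mul(a$den, b$den))
}

rat_div <- function(a, b) {
  b <- as_rat(b)
  if (poly_is_zero(b$num)) stop("division by zero rational function")
  rat_mul(a, new_rat(b$den, b$num))
}

#' Evaluate a rational function of the laziness parameters
#'
#' @param r an `lrw_rat` (as returned inside symbolic absorption results).
#' @param vals named numeric vector of variable values.
#' @return numeric scalar (`Inf` when only the denominator vanishes).
#' @export
rat_eval <- function(r, vals = numeric(0)) {
  r <- as_rat(r)
  num <- poly_eval(r$num, vals); den <- poly_eval(r$den, vals)
  if (abs(den) < 1e-300) {
    if (abs(num) < 1e-12) return(NaN)
    return(sign(num) * Inf)
  }
  num / den
}

#' @rdname rat_eval
#' @param var variable to differentiate with respect to.
#' @export
rat_deriv <- function(r, var) {
  r <- as_rat(r)
  new_rat(poly_add(poly_mul(poly_deriv(r$num, var), r$den),
                   poly_neg(poly_mul(r$num, poly_deriv(r$den, var)))),
          poly_mul(r$den, r$den))
}

#' @rdname poly_equal
#' @export
rat_equal <- function(a, b, tol = 1e-9) {
  a <- as_rat(a); b <- as_rat(b)
  poly_equal(poly_mul(a$num, b$den), poly_mul(b$num, a$den), tol = tol)
}

#' @export
format.lrw_rat <- function(x, ...) {
  paste0("(", format(x$num), ") / (", format(x$den), ")")
}

#' @export
print.lrw_rat <- function(x, ...) {
  cat("<rational function> ", format(x), "\n", sep = "")
  invisible(x)
}

# determinant of a list-matrix of polynomials by Laplace expansion along the
# first column (no division, so degrees stay minimal)
poly_det <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(as_poly(A[[1L, 1L]]))
  acc <- poly_const(0)
  for (i in seq_len(n)) {
    e <- as_poly(A[[i, 1L]])
    if (poly_is_zero(e)) next
    minor <- A[-i, -1L, drop = FALSE]
    term <- poly_mul(e, poly_det(minor))
    if (i %% 2L == 0L) term <- poly_neg(term)
    acc <- poly_add(acc, term)
  }
  acc
}

# Solve A x = b over the rational-function field by Cramer's rule (all
# entries polynomials; every solution component shares the determinant as
# denominator, keeping degrees minimal — no multivariate GCD needed).
# Exact up to floating error in the (dyadic) coefficients.
rat_solve <- function(A, b) {
  n <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == n)
  if (n > 8L) stop("symbolic solve limited to 8 states; evaluate numerically")
  M <- matrix(lapply(A, function(e) {
    if (is_rat(e)) stop("rat_solve expects polynomial entries")
    as_poly(e)
  }), n, n)
  bp <- lapply(b, as_poly)
  det_A <- poly_det(M)
  if (poly_is_zero(det_A)) stop("singular symbolic system (structurally)")
  lapply(seq_len(n), function(j) {
    Mj <- M
    for (i in seq_len(n)) Mj[[i, j]] <- bp[[i]]
    new_rat(poly_det(Mj), det_A)
  })
}
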