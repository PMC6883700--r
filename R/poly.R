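# QPolynomial construction, arithmetic and the exposed division primitives.

.qp_list <- function(p) list(exps = p@exps, coefs = p@coefs)

.qp_from_list <- function(l, vars) {
  exps <- l$exps
  if (!is.matrix(exps)) exps <- matrix(as.integer(exps), ncol = length(vars))
  storage.mode(exps) <- "integer"
  new("QPolynomial", vars = vars, exps = exps, coefs = as.character(l$coefs))
}

.qp_canon <- function(p) .qp_from_list(cpp_poly_scale(.qp_list(p), "1"), p@vars)

#' Construct a polynomial from exponents and coefficients
#'
#' @param vars character vector of variable names
#' @param exps integer matrix (terms x variables) of exponents; may be empty
#'   for the zero polynomial
#' @param coefs coefficients: rational strings or numerics
#' @return a [QPolynomial] in canonical form
#' @examples
#' # 16*y - x^2 - x*y - 1.5*x over (x, y)
#' qpoly(c("x", "y"),
#'       rbind(c(0, 1), c(2, 0), c(1, 1), c(1, 0)),
#'       c("16", "-1", "-1", "-1.5"))
#' @export
qpoly <- function(vars, exps = matrix(0L, 0, length(vars)), coefs = character()) {
  if (!is.matrix(exps)) exps <- matrix(as.integer(exps), ncol = length(vars), byrow = TRUE)
  storage.mode(exps) <- "integer"
  coefs <- if (is.numeric(coefs)) rationalize(format(coefs, digits = 17)) else as.character(coefs)
  p <- new("QPolynomial", vars = vars, exps = exps, coefs = coefs)
  .qp_canon(p)
}

#' @rdname qpoly
#' @param value a rational string or numeric scalar
#' @export
qpConst <- function(vars, value) {
  v <- if (is.numeric(value)) rationalize(format(value, digits = 17)) else cpp_rat_norm(value)
  if (identical(v, "0")) return(qpoly(vars))
  qpoly(vars, matrix(0L, 1, length(vars)), v)
}

#' @rdname qpoly
#' @param name a variable name contained in `vars`
#' @export
qpVar <- function(vars, name) {
  j <- match(name, vars)
  if (is.na(j)) stop("unknown variable: ", name)
  e <- matrix(0L, 1, length(vars))
  e[1, j] <- 1L
  qpoly(vars, e, "1")
}

.qp_check_compat <- function(a, b) {
  if (identical(a@vars, b@vars)) return(b)
  if (setequal(a@vars, b@vars)) return(.reorder_poly(b, a@vars))
  stop("polynomials are defined over different variable sets")
}

.qp_coerce <- function(x, template) {
  if (is(x, "QPolynomial")) return(x)
  if (is.numeric(x) || is.character(x)) return(qpConst(template@vars, x))
  stop("cannot coerce to polynomial: ", class(x)[1])
}

#' @describeIn QPolynomial-class arithmetic (`+`, `-`, `*`, `^`) between
#'   polynomials and rational/numeric scalars
#' @param e1,e2 operands
#' @export
setMethod("Arith", signature("QPolynomial", "ANY"), function(e1, e2) {
  op <- .Generic
  if (op == "^") {
    stopifnot(is.numeric(e2), e2 == round(e2), e2 >= 0)
    return(.qp_from_list(cpp_poly_pow(.qp_list(e1), as.integer(e2)), e1@vars))
  }
  e2 <- .qp_check_compat(e1, .qp_coerce(e2, e1))
  cppop <- switch(op, "+" = "add", "-" = "sub", "*" = "mul",
                  stop("unsupported polynomial operation: ", op))
  .qp_from_list(cpp_poly_arith(cppop, .qp_list(e1), .qp_list(e2)), e1@vars)
})

#' @describeIn QPolynomial-class scalar (op) polynomial
#' @export
setMethod("Arith", signature("ANY", "QPolynomial"), function(e1, e2) {
  e1 <- .qp_coerce(e1, e2)
  callGeneric(e1, e2)
})

#' @describeIn QPolynomial-class unary minus / polynomial-polynomial arithmetic
#' @export
setMethod("Arith", signature("QPolynomial", "QPolynomial"), function(e1, e2) {
  op <- .Generic
  e2 <- .qp_check_compat(e1, e2)
  cppop <- switch(op, "+" = "add", "-" = "sub", "*" = "mul",
                  stop("unsupported polynomial operation: ", op))
  .qp_from_list(cpp_poly_arith(cppop, .qp_list(e1), .qp_list(e2)), e1@vars)
})

setMethod("-", signature("QPolynomial", "missing"), function(e1, e2) {
  .qp_from_list(cpp_poly_scale(.qp_list(e1), "-1"), e1@vars)
})

#' @export
setMethod("variables", "QPolynomial", function(x) x@vars)

#' Is a polynomial identically zero?
#' @param p a [QPolynomial]
#' @return logical
#' @export
qpIsZero <- function(p) nrow(p@exps) == 0L

#' Total degree of a polynomial
#' @param p a [QPolynomial]
#' @return integer (-1 for the zero polynomial)
#' @export
qpDegree <- function(p) if (qpIsZero(p)) -1L else as.integer(max(rowSums(p@exps)))

#' Degree in a single variable
#' @param p a [QPolynomial]
#' @param var variable name
#' @return integer
#' @export
qpDegreeIn <- function(p, var) {
  j <- match(var, p@vars)
  if (is.na(j)) stop("unknown variable: ", var)
  if (qpIsZero(p)) return(-1L)
  max(p@exps[, j])
}

#' Variables actually present in a polynomial
#' @param p a [QPolynomial]
#' @return character vector
#' @export
qpVarsUsed <- function(p) {
  if (qpIsZero(p)) return(character())
  p@vars[colSums(p@exps) > 0]
}

#' Partial derivative
#' @param p a [QPolynomial]
#' @param var variable name
#' @return a [QPolynomial]
#' @export
qpDeriv <- function(p, var) {
  j <- match(var, p@vars)
  if (is.na(j)) stop("unknown variable: ", var)
  .qp_from_list(cpp_poly_deriv(.qp_list(p), j - 1L), p@vars)
}

#' Substitute an exact rational value for a variable
#' @param p a [QPolynomial]
#' @param var variable name
#' @param value rational string or numeric
#' @return a [QPolynomial] no longer containing `var`
#' @export
qpSubstRat <- function(p, var, value) {
  j <- match(var, p@vars)
  if (is.na(j)) stop("unknown variable: ", var)
  v <- if (is.numeric(value)) rationalize(format(value, digits = 17)) else cpp_rat_norm(value)
  .qp_from_list(cpp_poly_subst_rat(.qp_list(p), j - 1L, v), p@vars)
}

#' Substitute a polynomial for a variable
#' @param p a [QPolynomial]
#' @param var variable name
#' @param q replacement [QPolynomial] over the same variables
#' @return a [QPolynomial]
#' @export
qpSubstPoly <- function(p, var, q) {
  q <- .qp_check_compat(p, q)
  j <- match(var, p@vars)
  if (is.na(j)) stop("unknown variable: ", var)
  .qp_from_list(cpp_poly_subst_poly(.qp_list(p), j - 1L, .qp_list(q)), p@vars)
}

#' Exact evaluation at a rational point
#' @param p a [QPolynomial]
#' @param point named character vector of rational values, one per variable
#' @return rational string
#' @export
qpEvalRat <- function(p, point) {
  pt <- vapply(p@vars, function(v) cpp_rat_norm(as.character(point[[v]])), character(1))
  cpp_poly_eval_rat(.qp_list(p), unname(pt))
}

#' Fast numeric evaluation
#' @param p a [QPolynomial]
#' @param point named numeric vector (one entry per variable of `p`)
#' @return double
#' @export
qpEvalNum <- function(p, point) {
  if (qpIsZero(p)) return(0)
  x <- as.numeric(point[p@vars])
  co <- cpp_rat_to_double(p@coefs)
  sum(co * apply(p@exps, 1, function(e) prod(x^e)))
}

#' Coefficients of a univariate polynomial, ascending
#'
#' @param p a [QPolynomial] involving only `var`
#' @param var variable name
#' @return character vector `c0, c1, ..., cn` of rational strings
#' @export
qpUniCoefs <- function(p, var) {
  other <- setdiff(qpVarsUsed(p), var)
  if (length(other))
    stop("polynomial is not univariate in ", var, " (also involves ",
         paste(other, collapse = ", "), ")")
  j <- match(var, p@vars)
  if (is.na(j)) stop("unknown variable: ", var)
  d <- if (qpIsZero(p)) 0L else max(p@exps[, j])
  out <- rep("0", d + 1L)
  if (!qpIsZero(p)) out[p@exps[, j] + 1L] <- p@coefs
  out
}

#' Build a univariate polynomial from ascending coefficients
#' @param var variable name
#' @param coefs ascending coefficients (rational strings or numerics)
#' @return a [QPolynomial] over the single variable `var`
#' @export
qpFromUniCoefs <- function(var, coefs) {
  coefs <- if (is.numeric(coefs)) rationalize(format(coefs, digits = 17)) else as.character(coefs)
  qpoly(var, matrix(seq_along(coefs) - 1L, ncol = 1), coefs)
}

# ---- formatting -------------------------------------------------------------

.fmt_rat <- function(s) {
  x <- cpp_rat_to_double(s)
  if (grepl("/", s) && nchar(s) > 12) sprintf("%.6g", x) else s
}

#' Human-readable polynomial string
#' @param p a [QPolynomial]
#' @return character scalar such as `"x^3 - 8*x^2 + 12*x"`
#' @export
formatPoly <- function(p) {
  if (qpIsZero(p)) return("0")
  parts <- vapply(seq_along(p@coefs), function(i) {
    mono <- character()
    for (j in seq_along(p@vars)) {
      e <- p@exps[i, j]
      if (e == 1) mono <- c(mono, p@vars[j])
      else if (e > 1) mono <- c(mono, paste0(p@vars[j], "^", e))
    }
    co <- p@coefs[i]
    neg <- startsWith(co, "-")
    if (neg) co <- substring(co, 2)
    co <- .fmt_rat(co)
    body <- if (!length(mono)) co
      else if (co == "1") paste(mono, collapse = "*")
      else paste(c(co, mono), collapse = "*")
    paste0(if (neg) "- " else "+ ", body)
  }, character(1))
  out <- paste(parts, collapse = " ")
  sub("^\\+ ", "", out)
}

setMethod("show", "QPolynomial", function(object) {
  cat("QPolynomial over (", paste(object@vars, collapse = ", "), "): ",
      formatPoly(object), "\n", sep = "")
})

# ---- the exposed division primitives ---------------------------------------

.reorder_poly <- function(p, ranking) {
  stopifnot(setequal(ranking, p@vars))
  if (identical(ranking, p@vars)) return(p)
  perm <- match(ranking, p@vars)
  .qp_canon(new("QPolynomial", vars = p@vars[perm],
                exps = p@exps[, perm, drop = FALSE], coefs = p@coefs))
}

#' Compare two monomials under a lexicographic order
#'
#' The first differing exponent along the ranking decides; a monomial with a
#' higher exponent in the highest-ranked differing variable is greater.
#'
#' @param m1,m2 integer exponent vectors (optionally named by variable)
#' @param order character ranking (highest first); defaults to the order of
#'   the vectors themselves
#' @return -1, 0 or 1
#' @examples
#' lexCompare(c(x = 2, y = 1), c(x = 1, y = 3))  # x^2 y > x y^3 under x > y
#' @export
lexCompare <- function(m1, m2, order = NULL) {
  if (!is.null(order)) {
    m1 <- m1[order]
    m2 <- m2[order]
  }
  if (length(m1) != length(m2)) stop("exponent vectors differ in length")
  cpp_lex_compare(as.integer(m1), as.integer(m2))
}

#' Multivariate polynomial division (normal form)
#'
#' Divides `p` by a list of polynomials under the lexicographic order given
#' by `ranking`; no term of the remainder is divisible by any divisor's
#' leading term, and `p - remainder` lies in the ideal generated by `basis`.
#'
#' @param p a [QPolynomial]
#' @param basis list of nonzero [QPolynomial] over the same variables
#' @param ranking lex ranking (highest first); defaults to the variable order
#' @return the remainder [QPolynomial]
#' @export
polyReduce <- function(p, basis, ranking = variables(p)) {
  if (!length(basis)) return(p)
  pr <- .reorder_poly(p, ranking)
  br <- lapply(basis, .reorder_poly, ranking = ranking)
  out <- .qp_from_list(cpp_poly_reduce(.qp_list(pr), lapply(br, .qp_list)), ranking)
  .reorder_poly(out, variables(p))
}

#' S-polynomial of two polynomials
#'
#' The lcm-scaled combination cancelling both leading terms; the core object
#' of Buchberger's completion.
#'
#' @param p,q nonzero [QPolynomial] over the same variables
#' @param ranking lex ranking (highest first)
#' @return a [QPolynomial]
#' @export
sPolynomial <- function(p, q, ranking = variables(p)) {
  q <- .qp_check_compat(p, q)
  if (qpIsZero(p) || qpIsZero(q)) stop("S-polynomial of a zero polynomial")
  pr <- .reorder_poly(p, ranking)
  qr <- .reorder_poly(q, ranking)
  out <- .qp_from_list(cpp_spoly(.qp_list(pr), .qp_list(qr)), ranking)
  .reorder_poly(out, variables(p))
}

#' Exact polynomial division
#'
#' @param p,q [QPolynomial] over the same variables
#' @return the quotient [QPolynomial], or `NULL` when `q` does not divide `p`
#' @export
polyExactDivide <- function(p, q) {
  q <- .qp_check_compat(p, q)
  res <- cpp_exact_div(.qp_list(p), .qp_list(q))
  if (is.null(res)) return(NULL)
  .qp_from_list(res, p@vars)
}

#' Leading term under a lex ranking
#' @param p a nonzero [QPolynomial]
#' @param ranking lex ranking (highest first)
#' @return list with `exps` (named integer vector) and `coef` (string)
#' @export
leadingTerm <- function(p, ranking = variables(p)) {
  if (qpIsZero(p)) stop("zero polynomial has no leading term")
  pr <- .reorder_poly(p, ranking)
  list(exps = setNames(pr@exps[1, ], pr@vars), coef = pr@coefs[1])
}
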